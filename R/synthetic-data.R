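#' @include annotation-io.R
NULL

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.randomProtein <- function(len) {
    paste(sample(.AA20, len, replace = TRUE), collapse = "")
}

#' Specification of a planted protein family
#'
#' @param familyId family label (e.g. `"CARF"`, `"WYL"`, `"cas10"`).
#' @param nMembers default number of members [generateFamily()] emits.
#' @param withinIdentity target identity of each member to the family
#'   seed sequence, in (0, 1].
#' @param seedLength length of the family seed sequence, residues.
#' @return A list of class `FamilySpec`.
#' @export
familySpec <- function(familyId, nMembers = 20L, withinIdentity = 0.75,
                       seedLength = 200L) {
    if (withinIdentity <= 0 || withinIdentity > 1)
        stop("withinIdentity must be in (0, 1]")
    if (seedLength < 10L) stop("seedLength too short")
    structure(list(familyId = familyId, nMembers = as.integer(nMembers),
                   withinIdentity = withinIdentity,
                   seedLength = as.integer(seedLength)),
              class = "FamilySpec")
}

#' Template for a CRISPR-Cas locus
#'
#' @param templateId template label.
#' @param trueType the planted system type (`"I"`, `"II"`, `"III-A"`,
#'   `"III-B"`).
#' @param geneFamilyList ordered cas family ids; must contain the
#'   signature family of `trueType`.
#' @return A list of class `LocusTemplate`.
#' @export
locusTemplate <- function(templateId, trueType, geneFamilyList) {
    sigs <- list("I" = "cas3", "II" = "cas9",
                 "III-A" = c("cas10", "csm2"),
                 "III-B" = c("cas10", "cmr5"))
    if (!trueType %in% names(sigs))
        stop("trueType must be one of I, II, III-A, III-B")
    if (!all(sigs[[trueType]] %in% geneFamilyList))
        stop("template lacks the signature famil(ies) of type ", trueType)
    structure(list(templateId = templateId, trueType = trueType,
                   geneFamilyList = geneFamilyList),
              class = "LocusTemplate")
}

#' Default family specifications and locus templates
#'
#' The default families are the query family (CARF), its most common
#' neighborhood associate (WYL) and the cas families used by the default
#' locus templates.  Each family is generated from its own independent
#' random seed so that between-family identity is background (~5-10%).
#'
#' @return `defaultFamilySpecs()`: a named list of [familySpec()]s;
#'   `defaultLocusTemplates()`: a list of [locusTemplate()]s covering
#'   types I, II, III-A and III-B.
#' @export
defaultFamilySpecs <- function() {
    specs <- list(
        familySpec("CARF", seedLength = 200L),
        familySpec("WYL", seedLength = 170L),
        familySpec("cas1", seedLength = 300L),
        familySpec("cas2", seedLength = 100L),
        familySpec("cas3", seedLength = 350L),
        familySpec("cas9", seedLength = 360L),
        familySpec("cas10", seedLength = 380L),
        familySpec("csm2", seedLength = 140L),
        familySpec("cmr5", seedLength = 150L),
        familySpec("csx19", seedLength = 120L),
        familySpec("csx15", seedLength = 160L))
    setNames(specs, vapply(specs, `[[`, character(1), "familyId"))
}

#' @rdname defaultFamilySpecs
#' @export
defaultLocusTemplates <- function() {
    list(locusTemplate("T-I", "I", c("cas3", "cas1", "cas2")),
         locusTemplate("T-II", "II", c("cas9", "cas1", "cas2")),
         locusTemplate("T-IIIA", "III-A",
                       c("cas10", "csm2", "csx19", "cas1", "cas2")),
         locusTemplate("T-IIIB", "III-B",
                       c("cas10", "cmr5", "cas1", "cas2")))
}

#' Configuration for a synthetic genome collection
#'
#' Defines the simulated study conditions: genus structure, genome
#' sizes, planted families, locus templates and the probabilities that
#' tie the query family to cas loci and its associate family to the
#' query.  With a fixed seed the generated file tree is byte-identical
#' across runs.
#'
#' Counts that downstream summaries must match exactly (the number of
#' partial-flagged background genes and of cas-free genomes) are
#' realized as `round(p * n)` with randomly sampled identity; the
#' per-gene association events (`carfNearCasProb`, `wylNearCarfProb`)
#' are Bernoulli draws and are recorded per event in the ground truth.
#'
#' @param seed integer RNG seed.
#' @param nGenera number of genera.
#' @param speciesPerGenus integer range `c(min, max)` of genomes per
#'   genus.
#' @param genesPerReplicon integer range of genes per replicon.
#' @param proteinLength integer range of background protein lengths.
#' @param familySpecs named list of [familySpec()]s; must contain
#'   entries for `queryFamily`, `associateFamily` and every family used
#'   by `locusTemplates`.
#' @param locusTemplates list of [locusTemplate()]s.
#' @param carfNearCasProb probability that the planted query gene lands
#'   within the neighborhood window of a cas locus.
#' @param wylNearCarfProb probability that the planted associate gene
#'   lands within the query gene's window.
#' @param partialFraction fraction of background genes flagged partial.
#' @param pseudoFraction fraction of background genes flagged pseudo.
#' @param casFreeProb fraction of genomes generated without any cas
#'   locus (rounded to a deterministic count).
#' @param lociPerGenome integer range of cas loci per cas-bearing
#'   genome.
#' @param windowK neighborhood half-width (genes) used for planting.
#' @param carfEffectorProb probability that a planted query protein
#'   carries a C-terminal effector domain in the emitted hit table.
#' @param queryFamily,associateFamily family ids for the planted query
#'   and associate genes.
#' @param indelRate per-position indel rate for family members
#'   (default 0; substitution-only evolution).
#' @return A list of class `SimulationConfig`.
#' @export
simulationConfig <- function(seed = 1L, nGenera = 8L,
                             speciesPerGenus = c(1L, 3L),
                             genesPerReplicon = c(60L, 90L),
                             proteinLength = c(100L, 400L),
                             familySpecs = defaultFamilySpecs(),
                             locusTemplates = defaultLocusTemplates(),
                             carfNearCasProb = 0.75,
                             wylNearCarfProb = 0.8,
                             partialFraction = 0.05,
                             pseudoFraction = 0.02,
                             casFreeProb = 0.1,
                             lociPerGenome = c(1L, 2L),
                             windowK = 10L,
                             carfEffectorProb = 0.5,
                             queryFamily = "CARF",
                             associateFamily = "WYL",
                             indelRate = 0) {
    probs <- c(carfNearCasProb, wylNearCarfProb, partialFraction,
               pseudoFraction, casFreeProb, carfEffectorProb, indelRate)
    if (any(probs < 0 | probs > 1))
        stop("probabilities must be in [0, 1]")
    rng <- function(r) { r <- as.integer(r); stopifnot(length(r) == 2L,
                                                       r[1] <= r[2]); r }
    cfg <- list(seed = as.integer(seed), nGenera = as.integer(nGenera),
                speciesPerGenus = rng(speciesPerGenus),
                genesPerReplicon = rng(genesPerReplicon),
                proteinLength = rng(proteinLength),
                familySpecs = familySpecs,
                locusTemplates = locusTemplates,
                carfNearCasProb = carfNearCasProb,
                wylNearCarfProb = wylNearCarfProb,
                partialFraction = partialFraction,
                pseudoFraction = pseudoFraction,
                casFreeProb = casFreeProb,
                lociPerGenome = rng(lociPerGenome),
                windowK = as.integer(windowK),
                carfEffectorProb = carfEffectorProb,
                queryFamily = queryFamily,
                associateFamily = associateFamily,
                indelRate = indelRate)
    need <- unique(c(queryFamily, associateFamily,
                     unlist(lapply(locusTemplates, `[[`,
                                   "geneFamilyList"))))
    miss <- setdiff(need, names(familySpecs))
    if (length(miss) > 0L)
        stop("familySpecs lacks entries for: ", paste(miss, collapse = ", "))
    # every locus (with its window margins) plus the two planted genes
    # must fit on the smallest replicon
    maxLocus <- max(vapply(locusTemplates, function(t)
        length(t$geneFamilyList), integer(1)))
    needGenes <- cfg$lociPerGenome[2] * (maxLocus + 2L * cfg$windowK + 2L) + 4L
    if (cfg$genesPerReplicon[1] < needGenes)
        stop("replicon too small to host requested loci: need at least ",
             needGenes, " genes per replicon for these locus templates ",
             "and windowK")
    structure(cfg, class = "SimulationConfig")
}

#' Generate one protein family by point substitution from a seed
#'
#' A random seed sequence is drawn, then each member is derived from it
#' by substituting `round((1 - withinIdentity) * length)` uniformly
#' chosen positions with a uniform draw over the other 19 residues, so
#' each member's identity to the seed is exactly `withinIdentity` (up to
#' rounding).  With `indelRate > 0`, single-residue insertions or
#' deletions are additionally applied at that per-position rate.
#'
#' Uses (and advances) the current RNG state; seed the RNG for
#' reproducibility.
#'
#' @param spec a [familySpec()].
#' @param n number of members (default `spec$nMembers`).
#' @param indelRate per-position indel rate (default 0).
#' @return Character vector of member sequences, with the seed sequence
#'   in attribute `"seed"` and each member's realized identity to the
#'   seed in attribute `"identityToSeed"`.
#' @export
generateFamily <- function(spec, n = spec$nMembers, indelRate = 0) {
    seed <- .randomProtein(spec$seedLength)
    members <- character(n)
    idents <- numeric(n)
    nMut <- round((1 - spec$withinIdentity) * spec$seedLength)
    seedChars <- strsplit(seed, "")[[1]]
    for (i in seq_len(n)) {
        ch <- seedChars
        if (nMut > 0L) {
            pos <- sample.int(spec$seedLength, nMut)
            for (p in pos) {
                ch[p] <- sample(setdiff(.AA20, ch[p]), 1L)
            }
        }
        idents[i] <- 1 - nMut / spec$seedLength
        if (indelRate > 0) {
            out <- character(0)
            for (p in seq_along(ch)) {
                ev <- runif(1)
                if (ev < indelRate / 2) next              # deletion
                out <- c(out, ch[p])
                if (ev >= indelRate / 2 && ev < indelRate)
                    out <- c(out, sample(.AA20, 1L))      # insertion
            }
            ch <- out
        }
        members[i] <- paste(ch, collapse = "")
    }
    structure(members, seed = seed, identityToSeed = idents)
}

# Draw one fresh member of a family from a stored seed sequence.
.familyMember <- function(seedChars, withinIdentity, indelRate = 0) {
    L <- length(seedChars)
    nMut <- round((1 - withinIdentity) * L)
    ch <- seedChars
    if (nMut > 0L) {
        pos <- sample.int(L, nMut)
        for (p in pos) ch[p] <- sample(setdiff(.AA20, ch[p]), 1L)
    }
    if (indelRate > 0) {
        out <- character(0)
        for (p in seq_along(ch)) {
            ev <- runif(1)
            if (ev < indelRate / 2) next
            out <- c(out, ch[p])
            if (ev >= indelRate / 2 && ev < indelRate)
                out <- c(out, sample(.AA20, 1L))
        }
        ch <- out
    }
    list(seq = paste(ch, collapse = ""), identity = 1 - nMut / L)
}

# Deterministic hit-table rows for a planted gene.
.plantHits <- function(proteinId, family, protLen, effector) {
    rows <- data.frame(protein_id = proteinId, family = family,
                       start = 1L, end = protLen, evalue = 1e-25,
                       score = 180, stringsAsFactors = FALSE)
    if (family == "CARF") {
        carfEnd <- min(130L, protLen - 10L)
        rows$end <- carfEnd
        rows <- rbind(rows, data.frame(
            protein_id = proteinId, family = "wHTH",
            start = carfEnd + 5L, end = min(carfEnd + 35L, protLen),
            evalue = 1e-12, score = 60, stringsAsFactors = FALSE))
        if (effector)
            rows <- rbind(rows, data.frame(
                protein_id = proteinId, family = "HEPN",
                start = min(carfEnd + 40L, protLen - 5L), end = protLen,
                evalue = 1e-15, score = 80, stringsAsFactors = FALSE))
    }
    rows
}

#' Generate a synthetic genome collection with ground truth
#'
#' Builds `nGenera` genera with 1 or more genomes each; every genome is
#' one linear replicon populated with unique random background proteins.
#' Cas loci are instantiated contiguously from randomly chosen
#' templates; one query-family (CARF) gene per genome is placed within
#' the neighborhood window of a cas locus with probability
#' `carfNearCasProb` (and always away from cas in the deterministically
#' chosen cas-free genomes), and one associate-family (WYL) gene is
#' placed within the query gene's window with probability
#' `wylNearCarfProb`.  Partial and pseudo flags are planted on
#' background genes only, so every planted-family count downstream is
#' exact.
#'
#' @param config a [simulationConfig()].
#' @param outDir if non-`NULL`, the collection is written there:
#'   `genomes/<id>.gbk`, `genomes/<id>.ptt` + `.faa`,
#'   `truth/*.tsv`, and `config.yaml`.
#' @return A list with elements `replicons` (named list of
#'   [Replicon-class], one per genome), `truth` (list of ground-truth
#'   `data.frame`s: `proteins`, `loci`, `events`, `taxa`, `hits`), and
#'   `dir` (`outDir` or `NULL`).
#' @export
generateCollection <- function(config, outDir = NULL) {
    stopifnot(inherits(config, "SimulationConfig"))
    set.seed(config$seed)
    k <- config$windowK
    # genus / species layout
    nSpecies <- sample(seq(config$speciesPerGenus[1],
                           config$speciesPerGenus[2]),
                       config$nGenera, replace = TRUE)
    genomeGenus <- rep(sprintf("Genus%02d", seq_len(config$nGenera)),
                       nSpecies)
    nGenomes <- length(genomeGenus)
    genomeIds <- sprintf("G%03d", seq_len(nGenomes))
    speciesNo <- unlist(lapply(nSpecies, seq_len))
    speciesNames <- sprintf("%s sp%02d", genomeGenus, speciesNo)
    # deterministic cas-free genome count
    nCasFree <- round(config$casFreeProb * nGenomes)
    casFree <- logical(nGenomes)
    if (nCasFree > 0L)
        casFree[sample.int(nGenomes, nCasFree)] <- TRUE
    # family seeds (independent per family)
    famSeeds <- lapply(config$familySpecs, function(sp)
        strsplit(.randomProtein(sp$seedLength), "")[[1]])
    replicons <- list()
    truthProteins <- list(); truthLoci <- list(); truthEvents <- list()
    truthHits <- list()
    lociCount <- 0L
    for (gi in seq_len(nGenomes)) {
        gid <- genomeIds[gi]
        rid <- paste0(gid, "_chr")
        nGenes <- sample(seq(config$genesPerReplicon[1],
                             config$genesPerReplicon[2]), 1L)
        slotFamily <- rep(NA_character_, nGenes)   # NA = background
        casIdx <- integer(0)
        lociHere <- list()
        if (!casFree[gi]) {
            nLoci <- sample(seq(config$lociPerGenome[1],
                                config$lociPerGenome[2]), 1L)
            for (li in seq_len(nLoci)) {
                tmpl <- config$locusTemplates[[
                    sample.int(length(config$locusTemplates), 1L)]]
                L <- length(tmpl$geneFamilyList)
                # loci are kept >= 2k + 2 slots apart so that no query
                # window can overlap two loci and gap-merging in locus
                # calling never joins independently planted loci
                ok <- FALSE
                for (attempt in seq_len(200L)) {
                    s <- sample.int(nGenes - L + 1L, 1L) - 1L  # 0-based
                    span <- seq(s, s + L - 1L)
                    sep <- length(casIdx) == 0L ||
                        min(abs(outer(span, casIdx, "-"))) >= 2L * k + 2L
                    if (sep && all(is.na(slotFamily[span + 1L]))) {
                        ok <- TRUE
                        break
                    }
                }
                if (!ok) next
                slotFamily[span + 1L] <- tmpl$geneFamilyList
                casIdx <- c(casIdx, span)
                lociCount <- lociCount + 1L
                lociHere[[length(lociHere) + 1L]] <- list(
                    locus_id = sprintf("L%04d", lociCount),
                    start_index = s, end_index = s + L - 1L,
                    template_id = tmpl$templateId,
                    true_type = tmpl$trueType,
                    families = paste(tmpl$geneFamilyList, collapse = ","))
            }
        }
        free <- which(is.na(slotFamily)) - 1L   # 0-based free slots
        nearCasSlots <- free[vapply(free, function(ix)
            length(casIdx) > 0L && min(abs(ix - casIdx)) <= k, logical(1))]
        farCasSlots <- setdiff(free, nearCasSlots)
        # --- query (CARF) placement
        wantNear <- !casFree[gi] && runif(1) < config$carfNearCasProb
        carfPool <- if (wantNear) nearCasSlots else farCasSlots
        if (length(carfPool) == 0L)
            carfPool <- if (wantNear) farCasSlots else nearCasSlots
        carfIdx <- if (length(carfPool) == 1L) carfPool
                   else sample(carfPool, 1L)
        carfNear <- length(casIdx) > 0L && min(abs(carfIdx - casIdx)) <= k
        slotFamily[carfIdx + 1L] <- config$queryFamily
        # --- associate (WYL) placement
        free <- which(is.na(slotFamily)) - 1L
        nearCarf <- free[abs(free - carfIdx) <= k]
        farCarf <- setdiff(free, nearCarf)
        wantSame <- runif(1) < config$wylNearCarfProb
        wylPool <- if (wantSame) nearCarf else farCarf
        if (length(wylPool) == 0L)
            wylPool <- if (wantSame) farCarf else nearCarf
        wylIdx <- if (length(wylPool) == 1L) wylPool else sample(wylPool, 1L)
        wylSame <- abs(wylIdx - carfIdx) <= k
        slotFamily[wylIdx + 1L] <- config$associateFamily
        # --- background completeness flags
        bg <- which(is.na(slotFamily))
        nPartial <- round(config$partialFraction * length(bg))
        nPseudo <- round(config$pseudoFraction * length(bg))
        flagged <- sample(bg, min(nPartial + nPseudo, length(bg)))
        partialSet <- head(flagged, nPartial)
        pseudoSet <- setdiff(flagged, partialSet)
        # --- build gene rows
        effector <- runif(1) < config$carfEffectorProb
        pos <- 0L
        rows <- vector("list", nGenes)
        for (ix in seq_len(nGenes)) {
            idx0 <- ix - 1L
            fam <- slotFamily[ix]
            pid <- sprintf("%s_p%04d", gid, ix)
            tag <- sprintf("%s_%04d", gid, ix)
            pseudo <- ix %in% pseudoSet
            partial <- ix %in% partialSet
            if (!is.na(fam)) {
                sp <- config$familySpecs[[fam]]
                mem <- .familyMember(famSeeds[[fam]], sp$withinIdentity,
                                     config$indelRate)
                seq <- mem$seq
                identity <- mem$identity
                product <- paste(fam, "domain protein")
            } else {
                plen <- sample(seq(config$proteinLength[1],
                                   config$proteinLength[2]), 1L)
                seq <- .randomProtein(plen)
                identity <- NA_real_
                product <- "hypothetical protein"
            }
            plen <- nchar(seq)
            gap <- sample(20:200, 1L)
            start <- pos + gap
            end <- start + 3L * plen + 2L
            pos <- end
            rows[[ix]] <- data.frame(
                locus_tag = tag, protein_id = if (pseudo) NA_character_
                                              else pid,
                start = start, end = end,
                strand = sample(c("+", "-"), 1L),
                product = product,
                protein_seq = if (pseudo) NA_character_ else seq,
                is_partial = partial, is_pseudo = pseudo, index = idx0,
                stringsAsFactors = FALSE)
            truthProteins[[length(truthProteins) + 1L]] <- data.frame(
                protein_id = pid, genome_id = gid, replicon_id = rid,
                index = idx0,
                family = if (is.na(fam)) "background" else fam,
                identity_to_seed = identity,
                is_partial = partial, is_pseudo = pseudo,
                stringsAsFactors = FALSE)
            if (!is.na(fam) && !pseudo) {
                truthHits[[length(truthHits) + 1L]] <-
                    .plantHits(pid, fam, plen,
                               fam == config$queryFamily && effector)
            }
        }
        g <- do.call(rbind, rows)
        lenBp <- max(g$end) + sample(20:200, 1L)
        replicons[[gid]] <- .newReplicon(gid, rid, lenBp, "linear", g)
        for (lh in lociHere)
            truthLoci[[length(truthLoci) + 1L]] <- data.frame(
                locus_id = lh$locus_id, genome_id = gid,
                replicon_id = rid, start_index = lh$start_index,
                end_index = lh$end_index, template_id = lh$template_id,
                true_type = lh$true_type, families = lh$families,
                stringsAsFactors = FALSE)
        truthEvents[[length(truthEvents) + 1L]] <- data.frame(
            genome_id = gid,
            carf_protein_id = sprintf("%s_p%04d", gid, carfIdx + 1L),
            carf_index = carfIdx, near_cas = carfNear,
            wyl_protein_id = sprintf("%s_p%04d", gid, wylIdx + 1L),
            wyl_index = wylIdx, wyl_same_window = wylSame,
            carf_effector = effector, cas_free = casFree[gi],
            stringsAsFactors = FALSE)
    }
    taxa <- data.frame(genome_id = genomeIds, genus = genomeGenus,
                       species = speciesNames,
                       genome_size_bp = vapply(replicons, lengthBp,
                                               integer(1)),
                       stringsAsFactors = FALSE)
    truth <- list(
        proteins = do.call(rbind, truthProteins),
        loci = if (length(truthLoci)) do.call(rbind, truthLoci)
               else NULL,
        events = do.call(rbind, truthEvents),
        taxa = taxa,
        hits = do.call(rbind, truthHits))
    rownames(truth$proteins) <- rownames(truth$events) <- NULL
    if (!is.null(truth$loci)) rownames(truth$loci) <- NULL
    rownames(truth$hits) <- NULL
    out <- list(replicons = replicons, truth = truth, dir = outDir,
                config = config)
    if (!is.null(outDir)) .writeCollection(out, outDir)
    out
}

.writeCollection <- function(coll, outDir) {
    dir.create(file.path(outDir, "genomes"), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(outDir, "truth"), showWarnings = FALSE)
    taxa <- coll$truth$taxa
    for (gid in names(coll$replicons)) {
        rep <- coll$replicons[[gid]]
        sp <- taxa$species[taxa$genome_id == gid]
        writeGenbank(rep, file.path(outDir, "genomes",
                                    paste0(gid, ".gbk")), species = sp)
        writePtt(rep, file.path(outDir, "genomes", paste0(gid, ".ptt")),
                 file.path(outDir, "genomes", paste0(gid, ".faa")))
    }
    for (nm in names(coll$truth)) {
        if (!is.null(coll$truth[[nm]]))
            .writeTsv(coll$truth[[nm]],
                      file.path(outDir, "truth", paste0(nm, ".tsv")))
    }
    cfg <- coll$config
    cfgOut <- cfg[setdiff(names(cfg), c("familySpecs", "locusTemplates"))]
    cfgOut$familySpecs <- lapply(cfg$familySpecs, unclass)
    cfgOut$locusTemplates <- lapply(cfg$locusTemplates, unclass)
    yaml::write_yaml(cfgOut, file.path(outDir, "config.yaml"))
    invisible(outDir)
}
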