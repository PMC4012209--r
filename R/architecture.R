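#' @include utils.R
NULL

#' Effector-domain configuration
#'
#' Families counted as catalytic (usually nuclease) effector domains
#' when fused C-terminal to a CARF domain, versus pure DNA-binding
#' domains; the two sets must be disjoint.
#'
#' @param effectorFamilies families classified as catalytic effectors.
#' @param dbdFamilies DNA-binding domain families.
#' @param carfFamilies labels recognized as the CARF domain.
#' @param evalueMax e-value cutoff applied to hit tables.
#' @return A list of class `EffectorConfig`.
#' @export
effectorConfig <- function(effectorFamilies = c("HEPN", "PIN", "RelE",
                                                "REase", "HD", "Ada",
                                                "HNH", "Csx15"),
                           dbdFamilies = c("wHTH", "6H"),
                           carfFamilies = "CARF",
                           evalueMax = 0.01) {
    if (length(intersect(effectorFamilies, dbdFamilies)) > 0L)
        stop("effector and DNA-binding family sets must be disjoint")
    structure(list(effectorFamilies = effectorFamilies,
                   dbdFamilies = dbdFamilies,
                   carfFamilies = carfFamilies,
                   evalueMax = evalueMax),
              class = "EffectorConfig")
}

#' Resolve overlapping domain hits into an architecture
#'
#' Hits for one protein are filtered at `evalue <= evalueMax`, then
#' kept greedily by ascending e-value (ties: higher score, then smaller
#' start); a hit is kept only if it overlaps every already-kept hit by
#' at most `maxOverlapFrac` of the shorter interval.  The result is
#' ordered by start coordinate.
#'
#' @param hits domain-hit `data.frame` for one protein (columns
#'   `protein_id`, `family`, `start`, `end`, `evalue`, `score`).
#' @param evalueMax e-value cutoff (default 0.01).
#' @param maxOverlapFrac maximum tolerated pairwise overlap, as a
#'   fraction of the shorter interval (default 0.3).
#' @return A `data.frame` of kept hits ordered by start (the domain
#'   architecture).
#' @export
resolveOverlaps <- function(hits, evalueMax = 0.01,
                            maxOverlapFrac = 0.3) {
    hits <- hits[hits$evalue <= evalueMax, , drop = FALSE]
    if (nrow(hits) == 0L) {
        return(hits)
    }
    if (length(unique(hits$protein_id)) > 1L)
        stop("resolveOverlaps expects hits for a single protein")
    ord <- order(hits$evalue, -hits$score, hits$start)
    hits <- hits[ord, , drop = FALSE]
    keep <- integer()
    for (i in seq_len(nrow(hits))) {
        ok <- TRUE
        for (j in keep) {
            ov <- min(hits$end[i], hits$end[j]) -
                max(hits$start[i], hits$start[j]) + 1L
            shorter <- min(hits$end[i] - hits$start[i],
                           hits$end[j] - hits$start[j]) + 1L
            if (ov > maxOverlapFrac * shorter) { ok <- FALSE; break }
        }
        if (ok) keep <- c(keep, i)
    }
    out <- hits[keep, , drop = FALSE]
    out <- out[order(out$start, out$end), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Architecture string
#'
#' @param arch resolved architecture from [resolveOverlaps()].
#' @return Family labels joined with `"+"` in start order, e.g.
#'   `"CARF+wHTH+HEPN"`; `""` for an empty architecture.
#' @export
architectureString <- function(arch) {
    paste(arch$family, collapse = "+")
}

#' Classify a CARF protein as effector-bearing or regulatory
#'
#' `effector_bearing` when a CARF domain is present and at least one
#' effector family lies strictly downstream of (at higher coordinates
#' than) a CARF interval; `regulatory_only` when CARF is present
#' without such a fusion; `no_carf` otherwise.  Non-effector, non-CARF
#' domains never change the classification.
#'
#' @param arch resolved architecture from [resolveOverlaps()].
#' @param cfg an [effectorConfig()].
#' @return One of `"effector_bearing"`, `"regulatory_only"`,
#'   `"no_carf"`.
#' @export
classifyEffector <- function(arch, cfg = effectorConfig()) {
    carf <- arch[arch$family %in% cfg$carfFamilies, , drop = FALSE]
    if (nrow(carf) == 0L) return("no_carf")
    eff <- arch[arch$family %in% cfg$effectorFamilies, , drop = FALSE]
    for (i in seq_len(nrow(eff)))
        if (any(eff$start[i] > carf$end)) return("effector_bearing")
    "regulatory_only"
}

#' The CARF linear sequence signature
#'
#' Position classes of the seven-residue motif [DN]X[ST]XXX[RK]
#' associated with the ligand-binding pocket of the CARF domain.
#'
#' @return A list of class `MotifPattern`: one character vector of
#'   allowed residues per position (`NULL` = any residue).
#' @export
motifPattern <- function() {
    structure(list(c("D", "N"), NULL, c("S", "T"), NULL, NULL, NULL,
                   c("R", "K")),
              class = "MotifPattern")
}

#' Scan a protein for a positional motif
#'
#' Slides the pattern along the sequence and reports all 1-based start
#' positions where every position class is satisfied (overlapping
#' matches included).
#'
#' @param seq protein sequence (character(1)), standard alphabet.
#' @param pattern a [motifPattern()]-style list of position classes.
#' @return Integer vector of match start positions.
#' @examples
#' scanMotif("NPTQQQKDASAAAR", motifPattern())   # 1 and 8
#' @export
scanMotif <- function(seq, pattern = motifPattern()) {
    .checkProtein(seq)
    ch <- strsplit(seq, "")[[1]]
    m <- length(pattern)
    n <- length(ch)
    if (n < m) return(integer(0))
    hits <- integer(0)
    for (s in seq_len(n - m + 1L)) {
        ok <- TRUE
        for (p in seq_len(m)) {
            cls <- pattern[[p]]
            if (!is.null(cls) && !(ch[s + p - 1L] %in% cls)) {
                ok <- FALSE
                break
            }
        }
        if (ok) hits <- c(hits, s)
    }
    hits
}
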