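# Chromosome fragmentation and free-end bookkeeping.

#' Partition chromosomes into fragments at critical lesions
#'
#' A chromosome cut by k lesions yields k+1 fragments partitioning (0, L).
#' Each lesion creates two sibling free ends co-located at the lesion's
#' spatial position (the right end of the upstream fragment and the left end
#' of the downstream fragment); natural telomeric ends are not free.  Exactly
#' one fragment per chromosome carries the centromere.
#'
#' @param lesions A `critical_lesions` frame (see [place_ion_cls()]).
#' @param karyotype A [human_karyotype()] frame.
#' @return Object of class `cl_fragments`: list with
#'   `fragments` (`id`, `chrom`, `start_mbp`, `end_mbp`, `length_mbp`,
#'   `centric`) and `ends` (`end_id`, `fragment`, `cl`, `x`, `y`, `z`).
#' @export
fragments_from_lesions <- function(lesions, karyotype = human_karyotype()) {
  if (nrow(lesions) > 0) {
    bad <- lesions$coord_mbp <= 0 |
      lesions$coord_mbp >= karyotype$length_mbp[lesions$chrom]
    if (any(bad))
      stop("lesion genomic coordinate outside its chromosome", call. = FALSE)
  }
  n_chrom <- nrow(karyotype)
  frags <- vector("list", n_chrom)
  ends <- vector("list", n_chrom)
  next_frag <- 0L
  for (c in seq_len(n_chrom)) {
    idx <- which(lesions$chrom == c)
    idx <- idx[order(lesions$coord_mbp[idx])]
    cuts <- lesions$coord_mbp[idx]
    bounds <- c(0, cuts, karyotype$length_mbp[c])
    k <- length(cuts)
    fid <- next_frag + seq_len(k + 1L)
    next_frag <- next_frag + k + 1L
    cen <- karyotype$centromere_mbp[c]
    frags[[c]] <- data.frame(
      id = fid, chrom = c,
      start_mbp = bounds[-(k + 2L)], end_mbp = bounds[-1L],
      centric = bounds[-(k + 2L)] < cen & cen < bounds[-1L])
    if (k > 0L) {
      ends[[c]] <- data.frame(
        fragment = as.vector(rbind(fid[-(k + 1L)], fid[-1L])),
        cl = rep(idx, each = 2L),
        x = rep(lesions$x[idx], each = 2L),
        y = rep(lesions$y[idx], each = 2L),
        z = rep(lesions$z[idx], each = 2L))
    }
  }
  fragments <- do.call(rbind, frags)
  fragments$length_mbp <- fragments$end_mbp - fragments$start_mbp
  ends <- if (all(vapply(ends, is.null, logical(1)))) {
    data.frame(fragment = integer(0), cl = integer(0),
               x = numeric(0), y = numeric(0), z = numeric(0))
  } else do.call(rbind, ends[!vapply(ends, is.null, logical(1))])
  ends <- data.frame(end_id = seq_len(nrow(ends)), ends, row.names = NULL)
  structure(list(fragments = fragments, ends = ends,
                 karyotype = karyotype),
            class = "cl_fragments")
}

#' Stochastic distance-dependent rejoining of free ends
#'
#' Free ends are visited in uniformly random order.  Each still-undecided end
#' draws among all other undecided ends (excluding its sibling born at the
#' same lesion, since restitution is forbidden) with weight
#' \eqn{\exp(-d/r_0)} on the end-to-end Euclidean distance d, or remains
#' permanently free with weight `c_free`; the weights are normalized to a
#' categorical draw.
#'
#' @param fragments A [fragments_from_lesions()] object.
#' @param kernel A [rejoining_kernel()].
#' @return Object of class `pairing`: list with `junctions` (m x 2 matrix of
#'   end ids) and `free` (vector of permanently free end ids); together they
#'   partition the free ends.
#' @export
rejoin <- function(fragments, kernel = rejoining_kernel()) {
  stopifnot(inherits(fragments, "cl_fragments"),
            inherits(kernel, "rejoining_kernel"))
  e <- fragments$ends
  res <- cpp_rejoin(cbind(e$x, e$y, e$z), as.integer(e$cl),
                    kernel$r0_um, kernel$c_free)
  structure(list(junctions = res$junctions, free = as.integer(res$free)),
            class = "pairing")
}

#' Classify rejoined fragments into aberration categories
#'
#' Builds the junction graph (nodes = fragments, edges = junctions); each
#' connected component is one chromosomal element.  A linear element with two
#' centromeres is a dicentric (an element with c >= 2 centromeres counts as
#' c - 1 dicentrics, the equivalent-dicentric convention); a cyclic element
#' with one centromere is a centric ring; an acentric element of total length
#' >= `visibility_mbp` is a (large, visible) deletion.
#'
#' @param pairing A [rejoin()] result.
#' @param fragments The matching [fragments_from_lesions()] object.
#' @param visibility_mbp Visibility threshold for deletions, Mbp (default 3).
#' @return Named integer vector of class `aberration_tally`: `dicentrics`,
#'   `centric_rings`, `deletions`, `dicentrics_plus_rings`.
#' @export
classify <- function(pairing, fragments, visibility_mbp = 3) {
  stopifnot(inherits(pairing, "pairing"), inherits(fragments, "cl_fragments"))
  e <- fragments$ends
  j <- pairing$junctions
  if (length(j) && max(j) > nrow(e))
    stop("pairing references unknown ends", call. = FALSE)
  f <- fragments$fragments
  tal <- cpp_classify(j, as.integer(e$fragment), f$centric,
                      f$length_mbp, visibility_mbp)
  structure(tal, class = "aberration_tally")
}
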