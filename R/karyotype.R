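# Reference human karyotype packaged as constants.

# GRCh38 chromosome lengths and centromere midpoints, Mbp (rounded).
.chrom_table <- data.frame(
  name = c(as.character(1:22), "X"),
  length_mbp = c(248.96, 242.19, 198.30, 190.21, 181.54, 170.81, 159.35,
                 145.14, 138.39, 133.80, 135.09, 133.28, 114.36, 107.04,
                 101.99, 90.34, 83.26, 80.37, 58.62, 64.44, 46.71, 50.82,
                 156.04),
  centromere_mbp = c(123.4, 93.9, 90.9, 50.0, 48.8, 59.8, 60.1, 45.2, 43.0,
                     39.8, 53.4, 35.5, 17.7, 17.2, 19.0, 36.8, 25.1, 18.5,
                     26.2, 28.1, 12.0, 15.0, 60.6),
  stringsAsFactors = FALSE
)

#' Human female (46,XX) karyotype
#'
#' Reference chromosome lengths and centromere positions (GRCh38, Mbp) for a
#' diploid 46,XX cell: two homologues of each autosome plus two X chromosomes.
#' The XX karyotype avoids single-copy Y bookkeeping and matches biodosimetry
#' convention for peripheral blood lymphocyte work.
#'
#' @return A data frame of class `karyotype` with one row per chromosome copy
#'   and columns `id`, `name`, `length_mbp`, `centromere_mbp`, plus an
#'   attribute `total_mbp` (total diploid DNA content in Mbp).
#' @examples
#' k <- human_karyotype()
#' nrow(k)          # 46
#' attr(k, "total_mbp")
#' @export
human_karyotype <- function() {
  k <- .chrom_table[rep(seq_len(nrow(.chrom_table)), each = 2L), ]
  k$name <- paste0(k$name, rep(c("a", "b"), times = nrow(.chrom_table)))
  k <- data.frame(id = seq_len(nrow(k)), k, row.names = NULL,
                  stringsAsFactors = FALSE)
  stopifnot(nrow(k) == 46L, all(k$centromere_mbp > 0),
            all(k$centromere_mbp < k$length_mbp))
  attr(k, "total_mbp") <- sum(k$length_mbp)
  class(k) <- c("karyotype", "data.frame")
  k
}
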