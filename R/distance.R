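#' Euclidean genetic distance matrix between varieties
#'
#' Distances are computed on 0/1 allele codes (inbred biallelic genotypes
#' coded 0/2 are halved), so the squared distance between two varieties is
#' the number of markers at which they carry different alleles: a distance
#' of 20 corresponds to 400 allele differences. Missing genotypes are
#' handled pairwise-complete with the sum rescaled by
#' `n_markers / n_complete` before the square root, the convention of
#' `stats::dist()`.
#'
#' @param genotypes Numeric matrix, varieties x markers, codes 0/2/`NA`
#'   (or already 0/1).
#' @return A symmetric numeric matrix of distances with zero diagonal.
#' @export
#' @examples
#' g <- rbind(a = c(0, 2, 2, 0), b = c(0, 2, 2, 0), c = c(2, 0, 0, 2))
#' euclidean_distance_matrix(g)
euclidean_distance_matrix <- function(genotypes) {
  stopifnot(is.matrix(genotypes), nrow(genotypes) >= 2)
  codes <- genotypes
  if (any(codes == 2L, na.rm = TRUE)) codes <- codes / 2
  d <- as.matrix(dist(codes, method = "euclidean"))
  bad <- which(!is.finite(d) & upper.tri(d), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    pairs <- apply(bad, 1, function(ij) {
      paste(rownames(d)[ij[1]], colnames(d)[ij[2]], sep = "/")
    })
    abort(paste0("distance undefined (no shared complete markers) for: ",
                 paste(unique(pairs), collapse = ", ")))
  }
  d
}
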