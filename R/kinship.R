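#' Kinship matrix from a pedigree
#'
#' Computes the kinship coefficient phi(i, j) — the probability that a
#' randomly drawn allele from i and one from j are identical by descent —
#' for every pair in the pedigree, by the standard recursion: founders are
#' mutually unrelated with phi(i, i) = 1/2; for a non-founder i with parents
#' f and m, phi(i, i) = (1 + phi(f, m)) / 2 and phi(i, j) = (phi(f, j) +
#' phi(m, j)) / 2 for any j that is not a descendant of i. Individuals are
#' ordered family-major with parents before offspring, so the matrix is
#' block diagonal with one block per family.
#'
#' @param ped a \code{\link{as_pedigree}} data frame (coerced if plain).
#' @return an object of class \code{"kinship_matrix"}: a list with
#'   \code{phi} (symmetric matrix, dimnames = individual ids),
#'   \code{sample_ids}, \code{family} (factor) and \code{family_blocks}
#'   (list of index ranges, one per family).
#' @examples
#' trio <- data.frame(family_id = 1, individual_id = c("d", "m", "c"),
#'                    father_id = c(NA, NA, "d"), mother_id = c(NA, NA, "m"),
#'                    sex = c(1, 2, 1))
#' k <- kinship_from_pedigree(trio)
#' k$phi["d", "c"]  # 0.25
#' @export
kinship_from_pedigree <- function(ped) {
  if (!inherits(ped, "pedigree")) ped <- as_pedigree(ped)
  n <- nrow(ped)
  id <- ped$individual_id
  phi <- matrix(0, n, n, dimnames = list(id, id))
  fi <- match(ped$father_id, id)
  mi <- match(ped$mother_id, id)
  for (i in seq_len(n)) {
    if (is.na(fi[i])) {
      phi[i, i] <- 0.5
    } else {
      f <- fi[i]; m <- mi[i]
      phi[i, i] <- 0.5 * (1 + phi[f, m])
      prev <- seq_len(i - 1L)
      v <- 0.5 * (phi[f, prev] + phi[m, prev])
      phi[i, prev] <- v
      phi[prev, i] <- v
    }
  }
  fam <- factor(ped$family_id, levels = unique(ped$family_id))
  new_kinship(phi, fam)
}

new_kinship <- function(phi, family) {
  stopifnot(nrow(phi) == length(family))
  ends <- cumsum(table(family)[levels(family)])
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  blocks <- Map(function(s, e) s:e, starts, ends)
  names(blocks) <- levels(family)
  structure(list(phi = phi, sample_ids = rownames(phi),
                 family = family, family_blocks = blocks),
            class = "kinship_matrix")
}

#' Restrict a kinship matrix to a sample subset
#'
#' Rows/columns are returned in the order of \code{sample_subset}; family
#' block ranges are recomputed. Subsetting can interleave families, in which
#' case entries between families remain zero but the matrix is no longer
#' literally block-contiguous; keep subsets family-major to preserve the
#' block structure the mixed model exploits.
#'
#' @param kinship a \code{"kinship_matrix"}.
#' @param sample_subset character vector of individual ids.
#' @export
block_view <- function(kinship, sample_subset) {
  idx <- match(sample_subset, kinship$sample_ids)
  if (anyNA(idx))
    stop("unknown sample ids: ",
         paste(sample_subset[is.na(idx)], collapse = ", "))
  fam <- droplevels(kinship$family[idx])
  new_kinship(kinship$phi[idx, idx, drop = FALSE], fam)
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat(sprintf("Kinship matrix: %d individuals, %d family blocks\n",
              length(x$sample_ids), length(x$family_blocks)))
  cat(sprintf("  mean off-diagonal phi within families: %.4f\n",
              mean_within_phi(x)))
  invisible(x)
}

mean_within_phi <- function(x) {
  vals <- unlist(lapply(x$family_blocks, function(b) {
    m <- x$phi[b, b, drop = FALSE]
    m[upper.tri(m)]
  }))
  if (!length(vals)) return(NA_real_)
  mean(vals)
}

#' Write a kinship matrix as a square TSV with header ids
#' @param kinship a \code{"kinship_matrix"}.
#' @param path output file.
#' @export
write_kinship <- function(kinship, path) {
  utils::write.table(kinship$phi, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

# 2 * phi: expected additive genetic relationship (diagonal 1 for
# non-inbred individuals); the covariance structure used by both the
# simulator and the mixed model.
additive_relationship <- function(kinship) 2 * kinship$phi
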