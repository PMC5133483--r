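#' Construct and validate a pedigree
#'
#' A pedigree is a data frame with one row per individual and columns
#' \code{family_id}, \code{individual_id}, \code{father_id}, \code{mother_id}
#' (both \code{NA} for founders) and \code{sex} (1 = male, 2 = female).
#' Validation enforces the rules the kinship recursion relies on: individual
#' ids unique, parents either both known (and present in the same family) or
#' both missing, and no ancestry cycles.
#'
#' @param df data frame with the columns above.
#' @return the validated data frame with class \code{"pedigree"}, sorted
#'   family-major with parents before offspring.
#' @export
as_pedigree <- function(df) {
  need <- c("family_id", "individual_id", "father_id", "mother_id", "sex")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("pedigree is missing columns: ", paste(miss, collapse = ", "))
  df$family_id <- as.character(df$family_id)
  df$individual_id <- as.character(df$individual_id)
  df$father_id <- as.character(df$father_id)
  df$mother_id <- as.character(df$mother_id)
  df$father_id[df$father_id %in% c("0", "")] <- NA_character_
  df$mother_id[df$mother_id %in% c("0", "")] <- NA_character_
  if (anyDuplicated(df$individual_id))
    stop("duplicated individual ids: ",
         paste(unique(df$individual_id[duplicated(df$individual_id)]),
               collapse = ", "))
  one_parent <- xor(is.na(df$father_id), is.na(df$mother_id))
  if (any(one_parent))
    stop("individuals with exactly one known parent (both must be known or ",
         "both missing): ",
         paste(df$individual_id[one_parent], collapse = ", "))
  for (col in c("father_id", "mother_id")) {
    known <- !is.na(df[[col]])
    bad <- known & !(df[[col]] %in% df$individual_id)
    if (any(bad))
      stop("unknown ", sub("_id", "", col), " ids: ",
           paste(unique(df[[col]][bad]), collapse = ", "))
    idx <- match(df[[col]][known], df$individual_id)
    if (any(df$family_id[idx] != df$family_id[known]))
      stop("parent and offspring in different families")
  }
  ord <- pedigree_topo_order(df)
  out <- df[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pedigree", "data.frame")
  out
}

# Kahn topological sort; errors on ancestry cycles. Returns row order,
# family-major then parents-before-offspring.
pedigree_topo_order <- function(df) {
  n <- nrow(df)
  id <- df$individual_id
  fi <- match(df$father_id, id)
  mi <- match(df$mother_id, id)
  indeg <- (!is.na(fi)) + (!is.na(mi))
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(fi[i], mi[i])) {
      if (!is.na(p)) children[[p]] <- c(children[[p]], i)
    }
  }
  order_in_fam <- integer(n)
  queue <- which(indeg == 0L)
  k <- 0L
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]
    k <- k + 1L
    order_in_fam[i] <- k
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (k < n)
    stop("pedigree contains an ancestry cycle involving: ",
         paste(id[order_in_fam == 0L], collapse = ", "))
  order(match(df$family_id, unique(df$family_id)), order_in_fam)
}

#' @export
print.pedigree <- function(x, ...) {
  nf <- length(unique(x$family_id))
  founders <- sum(is.na(x$father_id))
  cat(sprintf("Pedigree: %d individuals in %d families (%d founders, %d non-founders)\n",
              nrow(x), nf, founders, nrow(x) - founders))
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

founder <- function(ped) is.na(ped$father_id)
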