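#' Read pedigrees from a PLINK-style FAM file
#'
#' Parses a whitespace- or tab-delimited file with columns
#' \code{family}, \code{id}, \code{father}, \code{mother}, \code{sex}
#' (a sixth phenotype column, if present, is ignored).  \code{"0"} codes a
#' missing parent; sex is coded 1 = male, 2 = female, 0 = unknown.
#'
#' @param path Path to the FAM file.
#' @return A named list of \code{pedigree} objects (one per family), each a
#'   data frame with columns \code{id}, \code{father}, \code{mother},
#'   \code{sex} (\code{NA} for a missing parent) in an order where parents
#'   precede offspring.
#' @export
read_pedigree <- function(path) {
  tab <- utils::read.table(path, header = FALSE, colClasses = "character",
                           col.names = paste0("V", 1:6), fill = TRUE)[, 1:5]
  names(tab) <- c("ped", "id", "father", "mother", "sex")
  if (any(tab$id == "" | is.na(tab$id)))
    stop("malformed FAM file: empty individual id")
  tab$father[tab$father == "0"] <- NA
  tab$mother[tab$mother == "0"] <- NA
  tab$sex <- match(tab$sex, c("1", "2"))           # 0/other -> NA = unknown
  peds <- lapply(split(tab, tab$ped), function(fam) {
    new_pedigree(fam$ped[1], fam$id, fam$father, fam$mother, fam$sex)
  })
  peds[unique(tab$ped)]
}

#' Construct and validate a single pedigree
#'
#' @param ped_id Pedigree (family) identifier.
#' @param id,father,mother Character vectors; \code{NA} for founder parents.
#' @param sex Integer vector, 1 = male, 2 = female, \code{NA} = unknown.
#' @return A \code{pedigree}: a data frame (\code{id}, \code{father},
#'   \code{mother}, \code{sex}) topologically sorted so every parent row
#'   precedes its offspring.
#' @export
new_pedigree <- function(ped_id, id, father, mother, sex = NA_integer_) {
  id <- as.character(id)
  if (anyDuplicated(id))
    stop(sprintf("pedigree %s: duplicate id '%s'", ped_id,
                 id[duplicated(id)][1]))
  for (p in c(father, mother)) {
    if (!is.na(p) && !p %in% id)
      stop(sprintf("pedigree %s: referenced parent '%s' not found", ped_id, p))
  }
  ped <- data.frame(id = id, father = as.character(father),
                    mother = as.character(mother),
                    sex = rep_len(as.integer(sex), length(id)),
                    stringsAsFactors = FALSE)
  ord <- topo_order(ped)
  ped <- ped[ord, , drop = FALSE]
  rownames(ped) <- NULL
  attr(ped, "ped_id") <- as.character(ped_id)
  class(ped) <- c("pedigree", "data.frame")
  ped
}

# Kahn topological sort; errors on cycles (an individual that is its own
# ancestor makes the parent graph cyclic).
topo_order <- function(ped) {
  n <- nrow(ped)
  fi <- match(ped$father, ped$id)
  mi <- match(ped$mother, ped$id)
  placed <- logical(n)
  ord <- integer(0)
  repeat {
    ready <- which(!placed &
                     (is.na(fi) | fi %in% which(placed)) &
                     (is.na(mi) | mi %in% which(placed)))
    if (!length(ready)) break
    placed[ready] <- TRUE
    ord <- c(ord, ready)
  }
  if (length(ord) < n)
    stop("cycle detected involving id(s) ",
         paste(ped$id[!placed], collapse = ", "))
  ord
}

#' Kinship matrix of a single pedigree
#'
#' Computes pairwise kinship coefficients by the standard recursion over a
#' topologically ordered pedigree: phi(i,i) = (1 + phi(f_i, m_i))/2 and
#' phi(i,j) = (phi(f_i, j) + phi(m_i, j))/2 for j preceding i, with terms
#' involving a missing parent equal to 0 (an unknown parent is treated as an
#' unrelated, non-inbred founder).
#'
#' @param ped A \code{pedigree}.
#' @return A symmetric matrix with \code{dimnames} set to the individual ids
#'   and attribute \code{scale = "kinship"}; diagonal 0.5 for non-inbred
#'   individuals.
#' @seealso [relationship_matrix()], [kinship_matrix()]
#' @export
kinship_from_pedigree <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  fi <- match(ped$father, ped$id)
  mi <- match(ped$mother, ped$id)
  phi <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    f <- fi[i]; m <- mi[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      pf <- if (is.na(f)) 0 else phi[f, j]
      pm <- if (is.na(m)) 0 else phi[m, j]
      phi[i, j] <- phi[j, i] <- (pf + pm) / 2
    }
    phi[i, i] <- 0.5 * (1 + if (is.na(f) || is.na(m)) 0 else phi[f, m])
  }
  structure(phi, scale = "kinship")
}

#' Block-diagonal kinship matrix across pedigrees
#'
#' Individuals in different pedigrees have kinship 0, so the cohort matrix is
#' block-diagonal with one block per pedigree.
#'
#' @param peds A list of \code{pedigree} objects (as from [read_pedigree()]).
#' @param scale \code{"kinship"} (raw phi, diagonal 0.5) or
#'   \code{"relationship"} (2 phi, the additive genetic covariance structure,
#'   diagonal 1 for non-inbred individuals).  The relationship scale is the
#'   default used by the variance model.
#' @return Symmetric matrix over all individuals with a \code{scale}
#'   attribute.
#' @export
kinship_matrix <- function(peds, scale = c("relationship", "kinship")) {
  scale <- match.arg(scale)
  if (inherits(peds, "pedigree")) peds <- list(peds)
  blocks <- lapply(peds, kinship_from_pedigree)
  ids <- unlist(lapply(blocks, rownames), use.names = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate individual ids across pedigrees: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  K <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  at <- 0L
  for (b in blocks) {
    idx <- at + seq_len(nrow(b))
    K[idx, idx] <- b
    at <- at + nrow(b)
  }
  K <- structure(K, scale = "kinship")
  if (scale == "relationship") relationship_matrix(K) else K
}

#' Convert a kinship matrix to the relationship (2 phi) scale
#'
#' @param K A kinship-scaled matrix (attribute \code{scale = "kinship"}).
#' @return The matrix with all entries doubled and \code{scale =
#'   "relationship"}; the diagonal becomes 1 + the inbreeding coefficient.
#' @export
relationship_matrix <- function(K) {
  sc <- attr(K, "scale")
  if (identical(sc, "relationship"))
    stop("matrix is already on the relationship scale")
  structure(2 * K, scale = "relationship", dimnames = dimnames(K))
}

# Clip tiny negative eigenvalues; error if clearly non-PSD.
check_psd <- function(A, tol = 1e-8) {
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  lo <- min(ev)
  if (lo < -tol * max(abs(ev), 1))
    stop(sprintf("matrix is not positive semidefinite (min eigenvalue %.3g)",
                 lo))
  if (lo < 0)
    warning(sprintf("clipping negative eigenvalue %.3g to 0 (numerical)", lo))
  invisible(A)
}

#' Write a kinship matrix to disk
#'
#' @param K Matrix from [kinship_matrix()].
#' @param path Output file.
#' @param format \code{"dense"}: tab-separated with a header row of ids;
#'   \code{"sparse"}: three columns \code{id1}, \code{id2}, \code{value} for
#'   the non-zero upper triangle (including the diagonal).
#' @return \code{path}, invisibly.
#' @export
write_kinship <- function(K, path, format = c("dense", "sparse")) {
  format <- match.arg(format)
  if (format == "dense") {
    df <- data.frame(id = rownames(K), K, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    ut <- which(upper.tri(K, diag = TRUE) & K != 0, arr.ind = TRUE)
    df <- data.frame(id1 = rownames(K)[ut[, 1]], id2 = colnames(K)[ut[, 2]],
                     value = K[ut])
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
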