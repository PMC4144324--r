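#' Read a transposed dosage table with its MAP sidecar
#'
#' The dosage file is tab-separated with SNPs as rows: a \code{snp_id}
#' header column followed by one column per individual; entries are allele
#' dosages 0, 1, 2 or \code{NA}.  The MAP file has columns \code{snp_id},
#' \code{chrom}, \code{pos} (1-based positions).
#'
#' @param dosage_path,map_path File paths.
#' @param ids Optional individual ids (e.g. from the pedigrees): columns not
#'   in \code{ids} are dropped with a warning; ids absent from the file
#'   raise an error.
#' @return A \code{genotypes} object (see [drop_genotypes()]); MAF is
#'   recomputed from the non-missing dosages.
#' @export
read_genotypes <- function(dosage_path, map_path, ids = NULL) {
  tab <- utils::read.table(dosage_path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  stopifnot(names(tab)[1] == "snp_id")
  snp_ids <- tab[[1]]
  dm <- as.matrix(tab[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(dm), nrow(dm), ncol(dm),
                                 dimnames = dimnames(dm)))
  bad <- which(!is.na(dm) & dm != "NA" &
                 (is.na(num) | !num %in% c(0, 1, 2)), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("invalid dosage '%s' at line %d of %s",
                 dm[bad[1, 1], bad[1, 2]], bad[1, 1] + 1L, dosage_path))
  dosage <- t(num)
  rownames(dosage) <- colnames(dm)
  colnames(dosage) <- snp_ids
  if (!is.null(ids)) {
    absent <- setdiff(ids, rownames(dosage))
    if (length(absent))
      stop("ids missing from genotype file: ", paste(absent, collapse = ", "))
    extra <- setdiff(rownames(dosage), ids)
    if (length(extra)) {
      warning("dropping ", length(extra),
              " genotype column(s) not in the pedigrees")
      dosage <- dosage[ids, , drop = FALSE]
    }
  }
  map <- utils::read.table(map_path, header = TRUE, sep = "\t")
  stopifnot(all(c("snp_id", "chrom", "pos") %in% names(map)))
  map <- map[match(snp_ids, map$snp_id), ]
  new_genotypes(dosage, map)
}

#' Read a long-format phenotype CSV
#'
#' @param path CSV with at least \code{id}, \code{age} and the value column;
#'   any further columns are kept as covariates.
#' @param value_col Name of the phenotype column.
#' @return A data frame.
#' @export
read_phenotypes <- function(path, value_col = "sbp") {
  ph <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "age", value_col)
  miss <- setdiff(need, names(ph))
  if (length(miss))
    stop("phenotype file lacks column(s): ", paste(miss, collapse = ", "))
  if (!nrow(ph)) stop("empty phenotype file")
  ph$id <- as.character(ph$id)
  ph
}

#' Cross-validate pedigree, genotype and phenotype inputs
#'
#' Checks id consistency across the three inputs, positivity of ages,
#' duplicate (individual, age) pairs, and tabulates individuals by number of
#' measurements.
#'
#' @param peds List of \code{pedigree} objects.
#' @param geno A \code{genotypes} object (optional).
#' @param pheno Phenotype data frame.
#' @return A \code{validation_report}: list with \code{ok}, \code{errors},
#'   \code{measurement_counts} (individuals with 1, 2, ... exams).
#' @export
validate_run <- function(peds, geno = NULL, pheno = NULL) {
  errors <- character(0)
  ped_ids <- unlist(lapply(peds, `[[`, "id"), use.names = FALSE)
  if (anyDuplicated(ped_ids))
    errors <- c(errors, paste("duplicate ids across pedigrees:",
                              paste(unique(ped_ids[duplicated(ped_ids)]),
                                    collapse = ", ")))
  counts <- NULL
  if (!is.null(pheno)) {
    if (!nrow(pheno)) errors <- c(errors, "phenotype table is empty")
    orphan <- setdiff(unique(pheno$id), ped_ids)
    if (length(orphan))
      errors <- c(errors, paste("phenotype ids not in any pedigree:",
                                paste(orphan, collapse = ", ")))
    if (any(pheno$age <= 0)) errors <- c(errors, "non-positive exam ages")
    dup <- duplicated(pheno[c("id", "age")])
    if (any(dup))
      errors <- c(errors, paste("duplicate (id, age) rows for:",
                                paste(unique(pheno$id[dup]), collapse = ", ")))
    if (nrow(pheno)) counts <- table(table(pheno$id))
  }
  if (!is.null(geno)) {
    orphan <- setdiff(rownames(geno$dosage), ped_ids)
    if (length(orphan))
      errors <- c(errors, paste("genotype ids not in any pedigree:",
                                paste(orphan, collapse = ", ")))
  }
  rep <- list(ok = !length(errors), errors = errors,
              measurement_counts = counts)
  class(rep) <- "validation_report"
  rep
}

#' @export
print.validation_report <- function(x, ...) {
  if (x$ok) cat("inputs consistent\n") else
    cat("validation errors:\n", paste(" -", x$errors, collapse = "\n"), "\n")
  if (!is.null(x$measurement_counts)) {
    cat("individuals by number of measurements:\n")
    print(x$measurement_counts)
  }
  invisible(x)
}

#' Writers for the cohort file formats
#'
#' \code{write_fam} writes the PLINK-style pedigree table (family, id,
#' father, mother, sex, phenotype placeholder); \code{write_dosage} the
#' transposed dosage TSV; \code{write_map} the SNP map; and
#' \code{write_phenotypes} the long-format phenotype CSV.  These round-trip
#' with [read_pedigree()], [read_genotypes()] and [read_phenotypes()].
#'
#' @param peds List of \code{pedigree} objects.
#' @param geno A \code{genotypes} object.
#' @param pheno Phenotype data frame.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @name cohort_writers
NULL

#' @rdname cohort_writers
#' @export
write_fam <- function(peds, path) {
  rows <- do.call(rbind, lapply(peds, function(p) {
    data.frame(ped = attr(p, "ped_id"), id = p$id,
               father = ifelse(is.na(p$father), "0", p$father),
               mother = ifelse(is.na(p$mother), "0", p$mother),
               sex = ifelse(is.na(p$sex), 0L, p$sex), pheno = -9L)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname cohort_writers
#' @export
write_dosage <- function(geno, path) {
  tab <- data.frame(snp_id = colnames(geno$dosage), t(geno$dosage),
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname cohort_writers
#' @export
write_map <- function(geno, path) {
  utils::write.table(geno$map, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname cohort_writers
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.csv(pheno, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the generative ground truth of a synthetic cohort as JSON
#'
#' @param cohort A \code{synthetic_cohort}.
#' @param path Output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_truth <- function(cohort, path) {
  cfg <- cohort$config
  cfg$causal <- NULL
  obj <- list(parameters = unclass(cfg),
              causal = cohort$truth$causal,
              individual = cohort$truth$individual)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write an association results table
#'
#' @param results An \code{assoc_result} data frame.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_assoc <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
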