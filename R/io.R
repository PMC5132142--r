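# Input parsing: delimited genotype matrices and the PLINK .raw additive
# dialect (FID/IID/PAT/MAT/SEX/PHENOTYPE prefix columns split off).

#' Read an additive-coded genotype matrix
#'
#' Accepts either a tab/comma-delimited matrix with a header of marker
#' names, or the PLINK `.raw` additive dialect, auto-detected from the
#' presence of the `FID`/`IID` prefix columns. In `.raw` input the
#' `FID IID PAT MAT SEX PHENOTYPE` columns are split off: `IID` becomes the
#' subject identifier and `PHENOTYPE` (recoded from PLINK's 1/2 to 0/1 when
#' applicable) is returned alongside the matrix.
#'
#' @param path Input file.
#' @param phenotype_column Optional column name to extract as the binary
#'   phenotype from a delimited file.
#' @return A list with `genotypes` (integer matrix with subject row names
#'   and marker column names) and `phenotype` (integer vector or `NULL`).
#' @export
read_genotypes <- function(path, phenotype_column = NULL) {
  dt <- data.table::fread(path, data.table = FALSE)
  cols <- names(dt)
  pheno <- NULL
  if (all(c("FID", "IID") %in% cols)) {
    subject_ids <- as.character(dt$IID)
    if ("PHENOTYPE" %in% cols) {
      pheno <- dt$PHENOTYPE
      if (all(pheno %in% c(1, 2))) pheno <- pheno - 1L  # PLINK 1/2 coding
      pheno <- as.integer(pheno)
    }
    drop <- intersect(c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"), cols)
    dt <- dt[, setdiff(cols, drop), drop = FALSE]
  } else {
    rn <- attr(dt, "row.names")
    subject_ids <- if (is.character(rn)) rn else paste0("S", seq_len(nrow(dt)))
    if (!is.null(phenotype_column)) {
      if (!phenotype_column %in% cols) {
        stop("phenotype column '", phenotype_column, "' not found")
      }
      pheno <- as.integer(dt[[phenotype_column]])
      dt <- dt[, setdiff(names(dt), phenotype_column), drop = FALSE]
    }
  }
  g <- as.matrix(dt)
  storage.mode(g) <- "integer"
  rownames(g) <- subject_ids
  .check_genotypes(g)
  list(genotypes = g, phenotype = pheno)
}

#' Read a two-column subject/phenotype file
#'
#' @param path File with columns `subject_id` and a 0/1 phenotype (header
#'   optional but recommended).
#' @param subject_ids Optional ordering: phenotype values are matched and
#'   reordered to these identifiers.
#' @return Integer 0/1 vector, named by subject.
#' @export
read_phenotype <- function(path, subject_ids = NULL) {
  dt <- data.table::fread(path, data.table = FALSE)
  if (ncol(dt) < 2L) stop("phenotype file needs two columns: subject_id, 0/1")
  y <- setNames(as.integer(dt[[2L]]), as.character(dt[[1L]]))
  if (!is.null(subject_ids)) {
    if (!all(subject_ids %in% names(y))) {
      stop("phenotype file is missing some subjects")
    }
    y <- y[as.character(subject_ids)]
  }
  if (!all(y %in% c(0L, 1L))) stop("phenotype values must be 0/1")
  y
}
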