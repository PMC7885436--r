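#' Methylation dataset container
#'
#' A light container for a CpG x sample methylation matrix together with an
#' optional detection-P matrix of the same shape and a probe annotation
#' table. Values are flagged as being on the beta scale (`[0, 1]`) or the
#' M scale (base-2 logit of beta).
#'
#' @param values Numeric matrix, CpGs in rows (unique rownames), samples in
#'   columns (colnames matching a sample sheet's `sample_id`).
#' @param scale `"M"` or `"beta"`.
#' @param detection_p Optional numeric matrix, same dimensions and dimnames
#'   as `values`.
#' @param annotation Optional probe annotation `data.frame` (see
#'   [read_probe_annotation()]); rows matched to `values` by `cpg_id`.
#' @return An object of class `MethylationDataset`: a list with elements
#'   `values`, `scale`, `detection_p`, `annotation`.
#' @export
methylation_dataset <- function(values, scale = c("M", "beta"),
                                detection_p = NULL, annotation = NULL) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("values must have CpG rownames")
  if (anyDuplicated(rownames(values))) stop("CpG ids must be unique")
  if (is.null(colnames(values))) stop("values must have sample colnames")
  if (scale == "beta" && any(values < 0 | values > 1, na.rm = TRUE))
    stop("beta-scale values must lie in [0, 1]")
  if (!is.null(detection_p)) {
    detection_p <- as.matrix(detection_p)
    if (!identical(dim(detection_p), dim(values)))
      stop("detection_p must have the same dimensions as values")
    dimnames(detection_p) <- dimnames(values)
  }
  if (!is.null(annotation)) {
    if (!"cpg_id" %in% names(annotation)) stop("annotation needs a cpg_id column")
    annotation <- annotation[match(rownames(values), annotation$cpg_id), ,
                             drop = FALSE]
  }
  structure(list(values = values, scale = scale, detection_p = detection_p,
                 annotation = annotation),
            class = "MethylationDataset")
}

#' @export
print.MethylationDataset <- function(x, ...) {
  cat(sprintf("MethylationDataset: %d CpGs x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale))
  cat(sprintf("  missing entries: %d; detection-P: %s; annotation: %s\n",
              sum(is.na(x$values)),
              if (is.null(x$detection_p)) "absent" else "present",
              if (is.null(x$annotation)) "absent" else "present"))
  invisible(x)
}

#' Convert a dataset between beta and M scales
#'
#' @param dataset A [methylation_dataset()].
#' @param eps Clamping bound passed to [m_from_beta()].
#' @return The dataset with `values` on the requested scale.
#' @export
as_m_dataset <- function(dataset, eps = 1e-6) {
  stopifnot(inherits(dataset, "MethylationDataset"))
  if (dataset$scale == "M") return(dataset)
  dataset$values <- m_from_beta(dataset$values, eps = eps)
  dataset$scale <- "M"
  dataset
}

#' @rdname as_m_dataset
#' @export
as_beta_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "MethylationDataset"))
  if (dataset$scale == "beta") return(dataset)
  dataset$values <- beta_from_m(dataset$values)
  dataset$scale <- "beta"
  dataset
}

#' Read a delimited methylation matrix
#'
#' Expects CpGs in rows (first column = CpG id) and samples in columns;
#' comma- or tab-delimited (sniffed from the header line).
#'
#' @param path File path.
#' @param scale Value scale of the file, `"M"` or `"beta"`.
#' @param detection_p_path Optional path to a detection-P matrix of
#'   identical layout.
#' @param annotation Optional annotation `data.frame`.
#' @return A [methylation_dataset()].
#' @export
read_methylation_matrix <- function(path, scale = c("M", "beta"),
                                    detection_p_path = NULL,
                                    annotation = NULL) {
  scale <- match.arg(scale)
  vals <- .read_matrix(path)
  dp <- if (!is.null(detection_p_path)) .read_matrix(detection_p_path)
  methylation_dataset(vals, scale = scale, detection_p = dp,
                      annotation = annotation)
}

.read_matrix <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Read a twin sample sheet
#'
#' Required columns: `sample_id`, `pair_id`, `member` (1/2), `zygosity`
#' (MZ/DZ), `wave` (1/2), `age`, `sex` (0/1 or F/M). Cell-type proportion
#' columns (`CD8T`, `CD4T`, `Bcell`, `Mono`, `Gran`, `NK`) are optional but
#' required by [adjust_cell_composition()].
#'
#' @param path CSV file path.
#' @return A validated `data.frame`.
#' @export
read_sample_sheet <- function(path) {
  validate_sample_sheet(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_sample_sheet
#' @param sheet A sample-sheet `data.frame` to validate in place.
#' @export
validate_sample_sheet <- function(sheet) {
  if (isTRUE(attr(sheet, "twinmeth_validated"))) return(sheet)
  need <- c("sample_id", "pair_id", "member", "zygosity", "wave", "age", "sex")
  miss <- setdiff(need, names(sheet))
  if (length(miss)) stop("sample sheet missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(sheet$sample_id)) stop("sample_id values must be unique")
  sheet$zygosity <- toupper(as.character(sheet$zygosity))
  if (!all(sheet$zygosity %in% c("MZ", "DZ")))
    stop("zygosity must be MZ or DZ")
  if (is.character(sheet$sex) || is.factor(sheet$sex))
    sheet$sex <- as.integer(toupper(as.character(sheet$sex)) %in% c("M", "MALE", "1"))
  if (!all(sheet$wave %in% c(1L, 2L))) stop("wave must be 1 or 2")
  zyg_per_pair <- tapply(sheet$zygosity, sheet$pair_id,
                         function(z) length(unique(z)))
  if (any(zyg_per_pair > 1)) stop("zygosity must be constant within a pair")
  counts <- table(sheet$pair_id, sheet$wave)
  if (any(counts > 2)) stop("a pair can have at most 2 members per wave")
  cells <- intersect(.CELL_TYPES, names(sheet))
  if (length(cells) && any(as.matrix(sheet[cells]) < 0, na.rm = TRUE))
    stop("cell proportions must be non-negative")
  attr(sheet, "twinmeth_validated") <- TRUE
  sheet
}

.CELL_TYPES <- c("CD8T", "CD4T", "Bcell", "Mono", "Gran", "NK")

#' Read a 450k-style probe annotation table
#'
#' Accepts either the package's own column names (`cpg_id`, `gene_group`,
#' `position`, `is_cpg_snp`, `maf`, `island_relation`) or the Illumina
#' manifest names (`Name`/`IlmnID`, `UCSC_RefGene_Group`, `MAPINFO`,
#' `Relation_to_Island`), which are normalised on read. Positions are
#' 1-based hg19 coordinates carried as metadata only.
#'
#' @param path CSV file path.
#' @return A `data.frame` with normalised column names.
#' @export
read_probe_annotation <- function(path) {
  ann <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  ren <- c(Name = "cpg_id", IlmnID = "cpg_id",
           UCSC_RefGene_Group = "gene_group", MAPINFO = "position",
           Relation_to_Island = "island_relation", MAF = "maf",
           CpG_SNP = "is_cpg_snp")
  for (old in names(ren)) {
    if (old %in% names(ann) && !ren[[old]] %in% names(ann))
      names(ann)[names(ann) == old] <- ren[[old]]
  }
  if (!"cpg_id" %in% names(ann)) stop("annotation needs a cpg_id (or Name) column")
  if ("gene_group" %in% names(ann)) {
    bad <- setdiff(unique(ann$gene_group),
                   c(.GENE_GROUPS, NA_character_, ""))
    if (length(bad)) stop("unknown gene_group values: ",
                          paste(bad, collapse = ", "))
  }
  if ("maf" %in% names(ann) &&
      any(ann$maf < 0 | ann$maf > 0.5, na.rm = TRUE))
    stop("maf must lie in [0, 0.5]")
  ann
}

.GENE_GROUPS <- c("TSS1500", "TSS200", "5'UTR", "1stExon", "Body", "3'UTR")
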