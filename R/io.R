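#' Read an expression matrix with sample labels
#'
#' Reads a tab-separated matrix (first column feature ids, header row of
#' sample ids) and a two-column labels file (`sample_id`, `class`) into a
#' [LabeledExpression-class] object. No filtering is applied here; the
#' low-variance filter is a separate, explicit step
#' ([lowVarianceFilter()]).
#'
#' @param matrixPath path to the TSV expression matrix.
#' @param labelsPath path to the TSV labels file.
#' @return a [LabeledExpression-class] object.
#' @export
readExpression <- function(matrixPath, labelsPath) {
  lines <- readLines(matrixPath)
  if (!length(lines)) stop("empty expression file: ", matrixPath)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  sampleIds <- header[-1L]
  if (anyDuplicated(sampleIds))
    stop("duplicate sample id(s) in ", matrixPath, ": ",
         paste(unique(sampleIds[duplicated(sampleIds)]), collapse = ", "))
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  featureIds <- vapply(body, `[`, character(1), 1L)
  if (anyDuplicated(featureIds))
    stop("duplicate feature id(s) in ", matrixPath, ": ",
         paste(unique(featureIds[duplicated(featureIds)]), collapse = ", "))
  values <- matrix(NA_real_, length(body), length(sampleIds),
                   dimnames = list(featureIds, sampleIds))
  for (i in seq_along(body)) {
    row <- body[[i]]
    if (length(row) != length(sampleIds) + 1L)
      stop("row ", i + 1L, " of ", matrixPath, " has ", length(row),
           " fields, expected ", length(sampleIds) + 1L)
    v <- suppressWarnings(as.numeric(row[-1L]))
    if (anyNA(v))
      stop("non-numeric value at row ", i + 1L, ", column ",
           which(is.na(v))[1L] + 1L, " of ", matrixPath)
    values[i, ] <- v
  }
  lab <- read.delim(labelsPath, header = TRUE, sep = "\t",
                    colClasses = "character")
  if (!all(c("sample_id", "class") %in% names(lab)))
    stop("labels file needs columns sample_id and class: ", labelsPath)
  missing <- setdiff(sampleIds, lab$sample_id)
  if (length(missing))
    stop("label missing for sample(s): ", paste(missing, collapse = ", "))
  LabeledExpression(values, setNames(lab$class, lab$sample_id))
}

#' Read a GMT gene-set file
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member...`. Duplicate member genes within a
#' line are collapsed.
#'
#' @param path path to the GMT file.
#' @param sourceNote optional provenance string stored on the collection.
#' @return a [GeneSetCollection-class] object.
#' @export
readGmt <- function(path, sourceNote = path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(GeneSetCollection(sourceNote = sourceNote))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop("GMT line ", short[1L], " has fewer than 3 fields: ", path)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[`, character(1), 1L)
  if (anyDuplicated(names(sets)))
    stop("duplicate pathway id(s) in ", path, ": ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  GeneSetCollection(sets, sourceNote = sourceNote)
}

#' Write a GeneSetCollection as GMT
#' @param x a [GeneSetCollection-class] object.
#' @param path output path.
#' @param description description field written on every line.
#' @return invisibly, `path`.
#' @export
writeGmt <- function(x, path, description = "na") {
  stopifnot(is(x, "GeneSetCollection"))
  sets <- geneSets(x)
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, description, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a miRNA target table
#'
#' Two-column TSV (`mirna_id`, `gene_id`), one edge per line.
#'
#' @param path path to the TSV file.
#' @return a [MirnaTargetMap-class] object.
#' @export
readTargets <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    colClasses = "character")
  if (!all(c("mirna_id", "gene_id") %in% names(tab)))
    stop("targets file needs columns mirna_id and gene_id: ", path)
  if (!nrow(tab)) return(MirnaTargetMap())
  MirnaTargetMap(split(tab$gene_id, tab$mirna_id))
}

#' Write a DEG / enrichment / ranking table as TSV
#' @param tab a data.frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeResultTable <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a miRNA network as JSON and an edge list
#'
#' @param network a [MirnaNetwork-class] object.
#' @param jsonPath output path for the JSON serialization.
#' @param edgesPath optional output path for a TSV edge list
#'   (mirna_id, gene_id, mi_bits, perm_p).
#' @return invisibly, `jsonPath`.
#' @export
writeNetwork <- function(network, jsonPath, edgesPath = NULL) {
  stopifnot(is(network, "MirnaNetwork"))
  obj <- list(pairs = networkPairs(network),
              mirnas = networkMirnas(network),
              regulated_genes = network@regulatedGenes,
              edges = networkEdges(network))
  jsonlite::write_json(obj, jsonPath, auto_unbox = FALSE, pretty = TRUE,
                       digits = NA)
  if (!is.null(edgesPath))
    writeResultTable(networkEdges(network), edgesPath)
  invisible(jsonPath)
}
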