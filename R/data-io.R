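## Readers and writers for the flat-file formats the pipeline consumes:
## expression TSV (features x samples), interaction edge lists, GMT gene
## sets, clinical tables, catalogue lists, and the protein -> gene-symbol
## mapping. All TSVs are tab-separated UTF-8; "" and "NA" parse as missing;
## the first header cell may be empty (common in TCGA flat exports).

.read_tsv_lines <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines[nzchar(lines)]
}

#' Read an expression matrix from TSV
#'
#' Expects a header row of sample ids (the first cell, naming the feature-id
#' column, may be empty) and one feature per row. Cells that are empty or
#' `"NA"` become missing values, never zeros.
#'
#' @param path TSV file path.
#' @param layer one of `"mrna"`, `"mirna"`, `"protein"`.
#' @param classPath optional two-column TSV (`sample`, `class`) assigning
#'   `"tumor"`/`"normal"` labels.
#' @return An [ExpressionLayer-class].
#' @export
readExpressionMatrix <- function(path, layer, classPath = NULL) {
  lines <- .read_tsv_lines(path)
  if (length(lines) < 2L) stop("expression file has no data rows: ", path)
  ## field count from separator count: strsplit() drops trailing empties,
  ## which must survive as missing cells
  nfield <- lengths(regmatches(lines, gregexpr("\t", lines, fixed = TRUE))) + 1L
  cells <- strsplit(lines, "\t", fixed = TRUE)
  cells <- lapply(seq_along(cells), function(i)
    c(cells[[i]], rep("", nfield[i] - length(cells[[i]]))))
  header <- cells[[1]]
  samples <- header[-1]
  if (!length(samples) || anyDuplicated(samples))
    stop("header must list unique sample ids")
  width <- length(header)
  body <- cells[-1]
  lens <- nfield[-1]
  if (any(lens != width)) {
    bad <- which(lens != width)[1]
    stop(sprintf("ragged row at line %d: %d fields, expected %d",
                 bad + 1L, lens[bad], width))
  }
  ids <- vapply(body, `[[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate feature id: ", paste(unique(dup), collapse = ", "))
  vals <- vapply(body, function(r) {
    v <- r[-1]
    v[v %in% c("", "NA")] <- NA_character_
    as.numeric(v)
  }, numeric(length(samples)))
  mat <- t(matrix(vals, nrow = length(samples),
                  dimnames = list(samples, ids)))
  cls <- NULL
  if (!is.null(classPath)) {
    cl <- utils::read.delim(classPath, header = TRUE,
                            colClasses = "character")
    cls <- stats::setNames(cl[[2]], cl[[1]])
    cls <- cls[names(cls) %in% samples]
  }
  ExpressionLayer(mat, layer, sampleClass = cls)
}

#' Write an expression layer to TSV
#'
#' Inverse of [readExpressionMatrix()]: a complete matrix round-trips
#' value-identically. Missing values are written as `NA`.
#'
#' @param x an [ExpressionLayer-class] or a named numeric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeExpressionMatrix <- function(x, path) {
  m <- if (is(x, "ExpressionLayer")) exprsMatrix(x) else x
  header <- paste(c("", colnames(m)), collapse = "\t")
  rows <- vapply(seq_len(nrow(m)), function(i)
    paste(c(rownames(m)[i], format(m[i, ], digits = 15, trim = TRUE,
                                   scientific = FALSE)),
          collapse = "\t"), character(1))
  writeLines(c(header, rows), path, useBytes = TRUE)
  invisible(path)
}

#' Restrict layers to their shared samples
#'
#' Returns the input layers restricted to the intersection of their sample
#' ids, all in one canonical (lexicographic) order. Needed because, e.g.,
#' protein data typically exist only for tumor samples.
#'
#' @param matrices list of [ExpressionLayer-class] objects (at least two).
#' @return list of layers with identical, lexicographically ordered samples.
#' @export
alignLayers <- function(matrices) {
  stopifnot(length(matrices) >= 2L)
  shared <- Reduce(intersect, lapply(matrices, colnames))
  if (!length(shared)) stop("empty sample intersection across layers")
  shared <- sort(shared)
  lapply(matrices, function(m) m[, shared])
}

#' Read a protein-to-gene-symbol mapping
#'
#' @param path two-column TSV (`protein_id`, `gene_symbol`), with or without
#'   a header line (detected by the literal column names).
#' @return named character vector: `protein_id -> gene_symbol`.
#' @export
readFeatureMapping <- function(path) {
  df <- utils::read.delim(path, header = FALSE, colClasses = "character")
  if (nrow(df) && tolower(df[1, 1]) %in% c("protein_id", "protein"))
    df <- df[-1, , drop = FALSE]
  mapping <- stats::setNames(df[[2]], df[[1]])
  if (anyDuplicated(names(mapping)))
    stop("a protein id maps to more than one symbol")
  if (any(!nzchar(mapping))) stop("empty gene symbols in mapping")
  mapping
}

#' Map protein features to gene symbols
#'
#' Renames the rows of a protein layer from platform protein ids to gene
#' symbols. Unmapped proteins are dropped (with a message giving the count).
#' When several proteins (isoforms, phospho-forms) map to one symbol the
#' collision is resolved per `collision`:
#' `"keep-most-complete"` (default) keeps the protein with the fewest
#' missing values, ties broken by lexicographically first protein id;
#' `"average"` averages the rows entry-wise (`NA`-aware); `"error"` aborts.
#'
#' @param protein an [ExpressionLayer-class] with `layer == "protein"`.
#' @param mapping named character vector from [readFeatureMapping()].
#' @param collision collision policy, see above.
#' @return An [ExpressionLayer-class] keyed by gene symbols.
#' @export
mapProteinFeatures <- function(protein, mapping,
                               collision = c("keep-most-complete",
                                             "average", "error")) {
  collision <- match.arg(collision)
  m <- exprsMatrix(protein)
  mapped <- rownames(m) %in% names(mapping)
  if (any(!mapped))
    message(sum(!mapped), " unmapped protein id(s) dropped")
  m <- m[mapped, , drop = FALSE]
  if (!nrow(m)) stop("no protein ids could be mapped")
  sym <- unname(mapping[rownames(m)])
  if (anyDuplicated(sym)) {
    if (collision == "error")
      stop("multiple proteins map to one symbol: ",
           paste(unique(sym[duplicated(sym)]), collapse = ", "))
    if (collision == "keep-most-complete") {
      ord <- order(vapply(seq_len(nrow(m)), function(i) sum(is.na(m[i, ])),
                          integer(1)), rownames(m))
      m <- m[ord, , drop = FALSE]
      sym <- sym[ord]
      keep <- !duplicated(sym)
      m <- m[keep, , drop = FALSE]
      sym <- sym[keep]
    } else { # average
      groups <- split(seq_len(nrow(m)), sym)
      m <- t(vapply(groups, function(ix)
        colMeans(m[ix, , drop = FALSE], na.rm = TRUE), numeric(ncol(m))))
      m[is.nan(m)] <- NA_real_
      sym <- names(groups)
    }
  }
  rownames(m) <- sym
  ExpressionLayer(m, "protein", sampleClass = sampleClass(protein))
}

#' Read an interaction edge list
#'
#' @param path TSV with columns `source`, `target` and optionally `effect`
#'   (`positive`/`negative`/`unknown`); a header row is detected by the
#'   literal word `source`.
#' @param role the declared table role, one of `"mirna_gene"`, `"mirna_tf"`,
#'   `"tf_gene"`, `"tf_mirna"`; stored as an attribute and used downstream
#'   to pick the right table for each regulatory test.
#' @return data.frame `source`, `target`, `effect` with attribute `role`;
#'   exact duplicate edges are dropped.
#' @export
readInteractionTable <- function(path, role = c("mirna_gene", "mirna_tf",
                                                "tf_gene", "tf_mirna")) {
  role <- match.arg(role)
  df <- utils::read.delim(path, header = FALSE, colClasses = "character")
  if (nrow(df) && tolower(df[1, 1]) == "source") df <- df[-1, , drop = FALSE]
  out <- data.frame(source = df[[1]], target = df[[2]],
                    effect = if (ncol(df) >= 3) df[[3]] else "unknown",
                    stringsAsFactors = FALSE)
  bad <- !out$effect %in% c("positive", "negative", "unknown")
  if (any(bad)) stop("invalid effect values in ", path)
  out <- out[!duplicated(out[c("source", "target")]), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "role") <- role
  out
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, `name<TAB>description<TAB>gene1<TAB>...`.
#'
#' @param path GMT file path.
#' @param source free-text source tag (GO/KEGG/BioCarta/...).
#' @return named list of character vectors with attribute `source`.
#' @export
readGeneSets <- function(path, source = "other") {
  lines <- .read_tsv_lines(path)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  names(cells) <- vapply(cells, `[[`, character(1), 1L)
  if (anyDuplicated(names(cells))) stop("duplicate gene-set names")
  sets <- lapply(cells, function(x) unique(x[-(1:2)]))
  if (any(lengths(sets) == 0L)) stop("empty gene sets in ", path)
  attr(sets, "source") <- source
  sets
}

#' Read a clinical table
#'
#' @param path TSV with header `sample`, `time_days`, `event`
#'   (event: 1 = death observed, 0 = censored).
#' @return data.frame `sample`, `time`, `event`.
#' @export
readClinicalTable <- function(path) {
  df <- utils::read.delim(path, header = TRUE, colClasses = "character")
  out <- data.frame(sample = df[[1]], time = as.numeric(df[[2]]),
                    event = as.integer(df[[3]]) != 0L,
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$sample)) stop("duplicate sample ids in clinical table")
  if (any(out$time < 0, na.rm = TRUE)) stop("negative survival times")
  out
}

#' Read a disease-miRNA catalogue (one id per line)
#' @param path text file path.
#' @return character vector of unique miRNA ids.
#' @export
readCatalogue <- function(path) {
  ids <- trimws(.read_tsv_lines(path))
  unique(ids[nzchar(ids)])
}

#' Read a PPI edge list
#' @param path two-column TSV of interacting gene symbols.
#' @return A [PPINetwork-class].
#' @export
readPPINetwork <- function(path) {
  df <- utils::read.delim(path, header = FALSE, colClasses = "character")
  if (nrow(df) && tolower(df[1, 1]) %in% c("a", "gene1", "source"))
    df <- df[-1, , drop = FALSE]
  PPINetwork(df)
}

#' Read externally produced biclusters
#'
#' Import path for bicluster results from an external tool: a two-column TSV
#' `module_id`, `member`, where members are either feature ids or sample ids
#' of `m` (assignment is by lookup).
#'
#' @param path TSV path.
#' @param m the [ExpressionLayer-class] the biclusters refer to.
#' @return list of [Bicluster-class] objects (score `NA`).
#' @export
readBiclustersTsv <- function(path, m) {
  df <- utils::read.delim(path, header = FALSE, colClasses = "character")
  if (nrow(df) && tolower(df[1, 1]) == "module_id") df <- df[-1, , drop = FALSE]
  feats <- rownames(m); samps <- colnames(m)
  lapply(split(df[[2]], df[[1]]), function(members) {
    rows <- intersect(members, feats)
    cols <- intersect(members, samps)
    unknown <- setdiff(members, c(feats, samps))
    if (length(unknown))
      stop("bicluster member not in matrix: ", unknown[1])
    new("Bicluster", rows = rows, cols = cols, score = NA_real_)
  })
}
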