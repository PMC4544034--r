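#' Read a gene-by-sample raw count matrix from TSV
#'
#' Expects a tab-separated file whose first column (header `gene_id`) holds
#' gene identifiers and whose remaining columns hold per-sample non-negative
#' integer counts. Row and column order are preserved.
#'
#' @param path Path to the TSV file.
#' @return An integer matrix with genes as rownames and samples as colnames.
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop("count matrix file needs a gene_id column plus at least one sample column")
  gene_ids <- df[[1L]]
  if (anyDuplicated(gene_ids)) {
    dup <- unique(gene_ids[duplicated(gene_ids)])
    stop("duplicate gene identifiers in ", path, ": ", paste(dup, collapse = ", "))
  }
  sample_ids <- colnames(df)[-1L]
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample identifiers in ", path, ": ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num) | num < 0 | num != round(num), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-integer or negative count at gene '%s', sample '%s' (value '%s')",
                 gene_ids[bad[1L, 1L]], sample_ids[bad[1L, 2L]],
                 vals[bad[1L, 1L], bad[1L, 2L]]))
  }
  counts <- matrix(as.integer(round(num)), nrow = length(gene_ids),
                   dimnames = list(gene_ids, sample_ids))
  counts
}

#' Write a count or expression matrix to TSV
#'
#' Inverse of [read_count_matrix()]: first column `gene_id`, one column per
#' sample, tab-separated, no quoting.
#'
#' @param mat Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_expression_matrix <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct phenotype labels for a two-class design
#'
#' @param sample_ids Character vector of unique sample identifiers.
#' @param class Integer vector (0/1) or logical, one entry per sample;
#'   class 0 is conventionally the reference ("solid tissue normal").
#' @param class_names Length-2 character vector naming classes 0 and 1
#'   (whitespace-free, since CLS tokens are space-separated).
#' @return A `phenotype_labels` object.
#' @export
phenotype_labels <- function(sample_ids, class,
                             class_names = c("solid_tissue_normal", "primary_tumor")) {
  stopifnot(length(sample_ids) == length(class), !anyDuplicated(sample_ids),
            length(class_names) == 2L)
  class <- as.integer(class)
  if (!all(class %in% c(0L, 1L))) stop("class must be coded 0/1")
  structure(list(sample_ids = as.character(sample_ids), class = class,
                 class_names = as.character(class_names)),
            class = "phenotype_labels")
}

#' @export
print.phenotype_labels <- function(x, ...) {
  cat(sprintf("phenotype_labels: %d samples (%d '%s', %d '%s')\n",
              length(x$sample_ids), sum(x$class == 0L), x$class_names[1L],
              sum(x$class == 1L), x$class_names[2L]))
  invisible(x)
}

#' Read two-class phenotype labels from a CLS file
#'
#' Standard 3-line CLS dialect: a header `<N> <k> 1`, a name line
#' `# name0 name1`, then N space-separated class tokens. Tokens may be the
#' class names or 0/1 indices; the first token encountered maps to class 0.
#'
#' @param path Path to the CLS file.
#' @return A [phenotype_labels()] object.
#' @export
read_cls <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3L) stop("CLS file must have 3 lines (header, names, tokens)")
  hdr <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  n <- as.integer(hdr[1L]); k <- as.integer(hdr[2L])
  if (is.na(n) || is.na(k)) stop("malformed CLS header line: ", lines[1L])
  if (k != 2L) stop("unsupported class count in CLS file: ", k, " (only 2-class designs supported)")
  name_line <- sub("^#\\s*", "", trimws(lines[2L]))
  class_names <- strsplit(name_line, "\\s+")[[1L]]
  if (length(class_names) != 2L) stop("CLS name line must list exactly 2 class names")
  tokens <- strsplit(trimws(lines[3L]), "\\s+")[[1L]]
  if (length(tokens) != n) {
    stop(sprintf("CLS declares %d samples but lists %d class tokens", n, length(tokens)))
  }
  levels <- unique(tokens)
  if (length(levels) != 2L) stop("CLS token line must contain exactly 2 distinct tokens")
  cls <- match(tokens, levels) - 1L
  # if tokens are the declared names, honor the name order instead of
  # first-encounter order so round trips are stable
  if (setequal(levels, class_names)) cls <- match(tokens, class_names) - 1L
  if (setequal(levels, c("0", "1"))) cls <- as.integer(tokens)
  phenotype_labels(sample_ids = sprintf("sample_%d", seq_len(n)),
                   class = cls, class_names = class_names)
}

#' Write two-class phenotype labels to a CLS file
#'
#' @param labels A [phenotype_labels()] object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_cls <- function(labels, path) {
  stopifnot(inherits(labels, "phenotype_labels"))
  n <- length(labels$sample_ids)
  nms <- gsub("\\s+", "_", labels$class_names)  # CLS tokens are space-separated
  lines <- c(sprintf("%d 2 1", n),
             paste("#", nms[1L], nms[2L]),
             paste(nms[labels$class + 1L], collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Construct a gene-set collection
#'
#' @param members Named list of character vectors (set name -> gene ids).
#' @param description Optional named character vector of set descriptions.
#' @return A `gene_set_collection` object (named list with a description attr).
#' @export
gene_set_collection <- function(members, description = NULL) {
  stopifnot(is.list(members))
  if (is.null(names(members)) || anyDuplicated(names(members))) {
    dup <- unique(names(members)[duplicated(names(members))])
    stop("gene set names must be unique and non-missing",
         if (length(dup)) paste0("; duplicated: ", paste(dup, collapse = ", ")))
  }
  for (nm in names(members)) {
    g <- members[[nm]]
    if (length(g) == 0L) stop("gene set '", nm, "' has an empty member list")
    if (anyDuplicated(g)) stop("gene set '", nm, "' contains duplicate genes")
  }
  if (is.null(description)) {
    description <- stats::setNames(rep("na", length(members)), names(members))
  }
  structure(members, description = description[names(members)],
            class = "gene_set_collection")
}

#' @export
`[.gene_set_collection` <- function(x, i) {
  out <- unclass(x)[i]
  gene_set_collection(out, attr(x, "description")[names(out)])
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sizes <- lengths(x)
  cat(sprintf("gene_set_collection: %d sets, sizes %d-%d\n",
              length(x), if (length(x)) min(sizes) else 0L,
              if (length(x)) max(sizes) else 0L))
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path Path to the GMT file.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  members <- list(); descr <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop(sprintf("GMT line %d has %d fields; need name, description and >=1 gene",
                   i, length(fields)))
    }
    nm <- fields[1L]
    if (nm %in% names(members)) stop("duplicate gene set name in GMT: ", nm)
    members[[nm]] <- fields[-c(1L, 2L)]
    descr[nm] <- fields[2L]
  }
  gene_set_collection(members, descr)
}

#' Write gene sets to a GMT file
#'
#' @param collection A [gene_set_collection()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  descr <- attr(collection, "description")
  lines <- vapply(names(collection), function(nm) {
    paste(c(nm, descr[[nm]], collection[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
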