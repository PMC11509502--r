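#' Construct an intensity matrix
#'
#' Container for a protein x sample table of non-negative label-free
#' intensities. A value of 0 means "not observed in this sample"; `NA`/`NaN`
#' cells are normalized to 0 at construction time, mirroring MaxQuant-style
#' label-free output where undetected proteins carry zero intensity.
#'
#' @param protein_ids character vector of unique protein accessions. Accession
#'   groups joined by semicolons (e.g. `"Q6GTX8; Q6ISS4"`) are kept verbatim
#'   as a single id.
#' @param sample_ids character vector of unique sample names.
#' @param values numeric matrix, one row per protein, one column per sample;
#'   all finite values must be non-negative.
#' @return An object of class `intensity_matrix` with fields `protein_ids`,
#'   `sample_ids` and `values` (a dimnamed numeric matrix).
#' @export
intensity_matrix <- function(protein_ids, sample_ids, values) {
  protein_ids <- as.character(protein_ids)
  sample_ids <- as.character(sample_ids)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != length(protein_ids) || ncol(values) != length(sample_ids))
    stop("values must be ", length(protein_ids), " x ", length(sample_ids))
  dup <- protein_ids[duplicated(protein_ids)]
  if (length(dup))
    stop("duplicate protein id: ", dup[1L])
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id: ", sample_ids[duplicated(sample_ids)][1L])
  values[is.na(values)] <- 0
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop("negative intensity at protein '", protein_ids[neg[1L, 1L]],
         "', sample '", sample_ids[neg[1L, 2L]], "'")
  dimnames(values) <- list(protein_ids, sample_ids)
  structure(list(protein_ids = protein_ids, sample_ids = sample_ids,
                 values = values),
            class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat("intensity_matrix:", length(x$protein_ids), "proteins x",
      length(x$sample_ids), "samples;",
      sprintf("%.1f%% zero cells\n", 100 * mean(x$values == 0)))
  invisible(x)
}

#' Construct a paired design
#'
#' Maps each subject to exactly one sample in each of two conditions. All
#' paired tests in the package operate through this mapping.
#'
#' @param subjects character vector of subject ids (unique).
#' @param condition_a,condition_b the two condition labels.
#' @param sample_a,sample_b character vectors, parallel to `subjects`: the
#'   sample id of each subject in condition A resp. B.
#' @return An object of class `paired_design` with fields `subjects`,
#'   `condition_a`, `condition_b` and `pairs` (a data frame with columns
#'   `subject`, `sample_a`, `sample_b`).
#' @export
paired_design <- function(subjects, condition_a, condition_b,
                          sample_a, sample_b) {
  subjects <- as.character(subjects)
  sample_a <- as.character(sample_a)
  sample_b <- as.character(sample_b)
  if (length(subjects) < 2L)
    stop("a paired design needs at least 2 subjects")
  if (anyDuplicated(subjects))
    stop("duplicate subject id: ", subjects[duplicated(subjects)][1L])
  if (length(sample_a) != length(subjects) ||
      length(sample_b) != length(subjects))
    stop("sample_a and sample_b must be parallel to subjects")
  all_samples <- c(sample_a, sample_b)
  if (anyDuplicated(all_samples))
    stop("sample id appears in more than one pair: ",
         all_samples[duplicated(all_samples)][1L])
  if (identical(as.character(condition_a), as.character(condition_b)))
    stop("condition labels must differ")
  structure(list(subjects = subjects,
                 condition_a = as.character(condition_a),
                 condition_b = as.character(condition_b),
                 pairs = data.frame(subject = subjects, sample_a = sample_a,
                                    sample_b = sample_b,
                                    stringsAsFactors = FALSE)),
            class = "paired_design")
}

#' @export
print.paired_design <- function(x, ...) {
  cat("paired_design:", length(x$subjects), "subjects;",
      x$condition_a, "vs", x$condition_b, "\n")
  invisible(x)
}

#' Construct a gene-set collection
#'
#' @param sets named list; each element a list with fields `description`
#'   (string) and `members` (character vector, non-empty, deduplicated).
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("set term ids must be unique and non-empty")
  sets <- lapply(sets, function(s) {
    m <- unique(as.character(s$members))
    m <- m[nzchar(m)]
    if (!length(m)) stop("gene set with empty member list")
    list(description = as.character(s$description %||% ""), members = m)
  })
  structure(sets, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection:", length(x), "sets; sizes",
      paste(range(vapply(x, function(s) length(s$members), 1L)),
            collapse = "-"), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a protein x sample intensity table
#'
#' Reads a tab-separated intensity table (MaxQuant proteinGroups-style
#' subset): a header row with an id column plus one column per sample.
#' Blank and `NA` cells are normalized to 0 ("not observed"); row order is
#' preserved.
#'
#' @param path path to a TSV file.
#' @param id_column name of the protein accession column
#'   (default `"Protein IDs"`).
#' @param drop_ids optional character vector of protein ids to drop after
#'   loading (e.g. contaminant/reverse accessions); default none.
#' @return An [intensity_matrix()].
#' @export
read_intensity_table <- function(path, id_column = "Protein IDs",
                                 drop_ids = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (!id_column %in% names(df))
    stop("id column '", id_column, "' not found in ", path)
  if (ncol(df) < 2L)
    stop("no sample columns in ", path)
  ids <- as.character(df[[id_column]])
  sample_cols <- setdiff(names(df), id_column)
  vals <- vapply(df[sample_cols], function(col) as.numeric(col),
                 numeric(nrow(df)))
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(NULL, sample_cols))
  m <- intensity_matrix(ids, sample_cols, vals)
  if (!is.null(drop_ids)) {
    keep <- !(m$protein_ids %in% drop_ids)
    m <- intensity_matrix(m$protein_ids[keep], m$sample_ids,
                          m$values[keep, , drop = FALSE])
  }
  m
}

#' Write an intensity matrix as TSV
#'
#' Inverse of [read_intensity_table()]; values are serialized with full
#' double precision so that a round trip is the identity.
#'
#' @param m an [intensity_matrix()].
#' @param path output path.
#' @param id_column header name for the accession column.
#' @export
write_intensity_table <- function(m, path, id_column = "Protein IDs") {
  df <- data.frame(id = m$protein_ids, stringsAsFactors = FALSE,
                   check.names = FALSE)
  names(df) <- id_column
  df <- cbind(df, as.data.frame(m$values, check.names = FALSE,
                                row.names = NULL))
  write_results_table(df, path)
}

#' Read a paired design table
#'
#' Reads a CSV with columns `subject`, `sample`, `condition` (extra columns
#' such as covariates are ignored). Exactly two condition labels must be
#' present and every subject must contribute exactly one sample per
#' condition. Condition A/B are assigned in order of first appearance in the
#' file.
#'
#' @param path path to a CSV file.
#' @return A [paired_design()].
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop("cannot parse design file ", path,
                                          ": ", conditionMessage(e)))
  need <- c("subject", "sample", "condition")
  if (nrow(df) == 0L)
    stop("design file is empty: ", path)
  if (!all(need %in% names(df)))
    stop("design file must have columns subject, sample, condition")
  conds <- unique(as.character(df$condition))
  if (length(conds) != 2L)
    stop("design must contain exactly 2 conditions, found ", length(conds),
         ": ", paste(conds, collapse = ", "))
  subjects <- unique(as.character(df$subject))
  pick <- function(subj, cond) {
    s <- df$sample[df$subject == subj & df$condition == cond]
    if (length(s) != 1L)
      stop("subject '", subj, "' has ", length(s), " samples in condition '",
           cond, "' (need exactly 1)")
    as.character(s)
  }
  paired_design(subjects, conds[1L], conds[2L],
                vapply(subjects, pick, "", cond = conds[1L]),
                vapply(subjects, pick, "", cond = conds[2L]))
}

#' Write a paired design table
#'
#' Long-format CSV inverse of [read_design()].
#'
#' @param d a [paired_design()].
#' @param path output path.
#' @export
write_design <- function(d, path) {
  df <- data.frame(
    subject = rep(d$subjects, 2L),
    sample = c(d$pairs$sample_a, d$pairs$sample_b),
    condition = rep(c(d$condition_a, d$condition_b),
                    each = length(d$subjects)),
    stringsAsFactors = FALSE)
  df <- df[order(match(df$subject, d$subjects)), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated fields
#' `term<TAB>description<TAB>member1<TAB>member2...`. Members are
#' deduplicated within each set.
#'
#' @param path path to a GMT file.
#' @return A [gene_set_collection()].
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[seq_len(max(which(nzchar(lines)), 0L))]  # trailing blanks ok
  if (!length(lines)) stop("empty GMT file: ", path)
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("GMT line ", i, " has ", length(f), " fields (need >= 3)")
    term <- f[1L]
    if (term %in% names(sets))
      stop("duplicate term id '", term, "' at GMT line ", i)
    sets[[term]] <- list(description = f[2L], members = f[-(1:2)])
  }
  gene_set_collection(sets)
}

#' Write a gene-set collection as GMT
#'
#' @param gsc a [gene_set_collection()].
#' @param path output path.
#' @export
write_gene_sets <- function(gsc, path) {
  lines <- vapply(names(gsc), function(term) {
    paste(c(term, gsc[[term]]$description, gsc[[term]]$members),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a result table as TSV
#'
#' Serializes a homogeneous record table (data frame) with a header row,
#' tab-separated, in the given row order. Floating point values keep full
#' precision (`%.17g`) so that write-then-read is the identity on values.
#'
#' @param rows a data frame (possibly with zero rows).
#' @param path output path.
#' @export
write_results_table <- function(rows, path) {
  if (!is.data.frame(rows))
    rows <- as.data.frame(do.call(rbind, lapply(rows, as.data.frame)))
  out <- rows
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- sprintf("%.17g", out[[j]])
      v[is.na(out[[j]])] <- "NA"
      out[[j]] <- v
    }
  }
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write ", path, ": ",
                                           conditionMessage(e)))
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read back a result table written by [write_results_table()]
#'
#' @param path path to a TSV file.
#' @return A data frame.
#' @export
read_results_table <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}
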