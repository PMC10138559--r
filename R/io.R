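# File-format adapters. All tables are TSV with one header row; floats are
# serialized at 6 significant digits; gene identifiers are opaque strings.

#' Read a gene x sample expression matrix from TSV
#'
#' First column `gene_id`, remaining columns one per sample. Duplicate gene
#' identifiers and non-numeric cells are hard errors (with coordinates).
#'
#' @param path file path.
#' @param is_log2 whether the stored values are log2-transformed (default
#'   `TRUE`, the format written by [write_expression_tsv()]).
#' @param pseudocount recorded for a later [log_transform()] call.
#' @return an [expression_matrix()].
#' @export
read_expression_tsv <- function(path, is_log2 = TRUE, pseudocount = 1) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop_input("expression TSV needs a gene_id column plus >= 1 sample: ", path)
  if (names(df)[1] != "gene_id")
    stop_input("first column must be 'gene_id', found '", names(df)[1], "'")
  genes <- df[[1]]
  dup <- unique(genes[duplicated(genes)])
  if (length(dup))
    stop_input("duplicated gene row(s): ", paste(utils::head(dup, 5), collapse = ", "))
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim(vals)))
  bad <- which(is.na(num) & !is.na(vals) & vals != "NA", arr.ind = TRUE)
  if (nrow(bad))
    stop_input(sprintf("non-numeric cell at row %d (gene %s), column '%s'",
                       bad[1, 1], genes[bad[1, 1]],
                       colnames(vals)[bad[1, 2]]))
  dimnames(num) <- list(genes, colnames(vals))
  expression_matrix(num, is_log2 = is_log2, pseudocount = pseudocount)
}

#' Write an expression matrix to TSV
#'
#' @param m an [expression_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(m, path) {
  stopifnot(inherits(m, "expression_matrix"))
  df <- data.frame(gene_id = rownames(m$values),
                   signif(m$values, 6), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a sample sheet
#'
#' CSV with columns `sample_id, platform, dose, time, cohort`
#' (cohort in `control`/`treated`).
#'
#' @param path file path.
#' @return data frame.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  ss <- utils::read.csv(path, colClasses = "character")
  need <- c("sample_id", "platform", "dose", "time", "cohort")
  miss <- setdiff(need, names(ss))
  if (length(miss))
    stop_input("sample sheet missing column(s): ", paste(miss, collapse = ", "))
  if (!all(ss$cohort %in% c("control", "treated")))
    stop_input("cohort must be 'control' or 'treated'")
  if (anyDuplicated(ss$sample_id)) stop_input("duplicate sample_id in sheet")
  ss[, need]
}

#' @rdname read_sample_sheet
#' @param sheet data frame as returned by [read_sample_sheet()].
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.csv(sheet, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gene-set collection from a GMT file
#'
#' Each line: set name, description, then one or more tab-separated gene
#' identifiers. Duplicate set names are errors; duplicate genes within a set
#' are deduplicated with a warning.
#'
#' @param path GMT file path.
#' @param kind `"injury_module"` or `"pathway"`.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path, kind = c("injury_module", "pathway")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop_input("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop_input("GMT file is empty: ", path)
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop_input("GMT line ", i, " has fewer than 3 tab-separated fields")
    nm <- f[1]
    if (nm %in% names(sets)) stop_input("duplicate gene-set name '", nm, "'")
    sets[[nm]] <- list(genes = f[-(1:2)], description = f[2])
  }
  gene_set_collection(sets, kind = kind)
}

#' Write a gene-set collection to GMT
#'
#' @param collection a [gene_set_collection()].
#' @param path output file path.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(collection$sets, function(s) {
    paste(c(s$name, if (nzchar(s$description)) s$description else "na",
            s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a fold-change profile TSV
#'
#' Columns `gene_id, log2_fc[, p_value, q_value]`; the condition is stored in
#' a `# condition:` header comment.
#'
#' @param profile a `fold_change_profile`.
#' @param path file path.
#' @export
write_profile_tsv <- function(profile, path) {
  stopifnot(inherits(profile, "fold_change_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  cond <- attr(profile, "condition")
  writeLines(paste0("# condition: ", condition_label(cond)), con)
  df <- as.data.frame(profile)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, 6)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_tsv
#' @export
read_profile_tsv <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  first <- readLines(path, n = 1L)
  cond <- list(platform = NA, dose = NA, time = NA)
  if (startsWith(first, "# condition: ")) {
    parts <- strsplit(sub("# condition: ", "", first), "_")[[1]]
    if (length(parts) >= 3L) {
      # platform labels may themselves contain underscores (e.g. in_vivo)
      n <- length(parts)
      cond <- list(platform = paste(parts[seq_len(n - 2)], collapse = "_"),
                   dose = parts[n - 1], time = parts[n])
    }
  }
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("gene_id", "log2_fc") %in% names(df)))
    stop_input("profile TSV needs gene_id and log2_fc columns")
  new_fc_profile(df, condition = cond, n_dropped = 0L)
}

md5_of <- function(paths) {
  h <- tools::md5sum(paths)
  stats::setNames(unname(h), basename(paths))
}
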