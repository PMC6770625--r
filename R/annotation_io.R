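NULL

# Internal coordinate convention: 0-based, half-open [start, end), as in BED.
# RepeatMasker .out (1-based, inclusive) is converted on read.

RE_CLASSES <- c("SINE", "LINE", "LTR_ERV", "OTHER")

#' Normalize a retroelement class token to the closed class set
#'
#' Tokens are matched case-insensitively; `LTR`, `ERV`, `LR/ERV` and
#' `LTR_ERV` all map to `LTR_ERV`. Anything unrecognised maps to `OTHER`
#' with a warning, so real RepeatMasker tables containing DNA transposons,
#' satellites etc. pass through.
#'
#' @param token character vector of raw class labels.
#' @return character vector over `SINE`, `LINE`, `LTR_ERV`, `OTHER`.
#' @export
normalize_re_class <- function(token) {
  tk <- toupper(sub("/.*$", "", trimws(token)))
  out <- rep("OTHER", length(tk))
  out[tk == "SINE"] <- "SINE"
  out[tk == "LINE"] <- "LINE"
  out[tk %in% c("LTR", "ERV", "LTR_ERV", "LR_ERV", "LR/ERV")] <- "LTR_ERV"
  unknown <- unique(token[out == "OTHER" & tk != "OTHER"])
  if (length(unknown))
    warning("unknown RE class token(s) mapped to OTHER: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  out
}

.read_lines_nocomment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ln <- readLines(path, warn = FALSE)
  keep <- !grepl("^#", ln) & nzchar(trimws(ln))
  list(lines = ln[keep], lineno = which(keep))
}

.split_fields <- function(lines, sep = "\t") {
  if (identical(sep, "ws")) strsplit(trimws(lines), "[ \t]+") else strsplit(lines, sep, fixed = TRUE)
}

.as_coord <- function(x, lineno, what) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(!is.finite(v) | v != floor(v))
  if (length(bad))
    stop("unparseable ", what, " at line ", lineno[bad[1]], call. = FALSE)
  as.integer(v)
}

.check_intervals <- function(start, end, lineno) {
  bad <- which(start < 0)
  if (length(bad)) stop("negative start at line ", lineno[bad[1]], call. = FALSE)
  bad <- which(end <= start)
  if (length(bad))
    stop("end <= start (empty or inverted interval) at line ", lineno[bad[1]],
         call. = FALSE)
  invisible(TRUE)
}

#' Read a gene table with strand-resolved TSS
#'
#' Supported dialects: `bed6` (chrom, start, end, name, score, strand; BED
#' 0-based half-open) and `tsv` (header with columns `gene_id`, `symbol`,
#' `chrom`, `start`, `end`, `strand`, same coordinate convention). The TSS is
#' the first transcribed base: `start` on the plus strand and `end - 1` on
#' the minus strand.
#'
#' @param path file path.
#' @param dialect `"bed6"` or `"tsv"`.
#' @return a `data.frame` with columns `gene_id`, `symbol`, `chrom`,
#'   `start`, `end`, `strand`, `tss`.
#' @export
read_gene_table <- function(path, dialect = c("bed6", "tsv")) {
  dialect <- match.arg(dialect)
  src <- .read_lines_nocomment(path)
  if (dialect == "bed6") {
    fl <- .split_fields(src$lines, "ws")
    n <- lengths(fl)
    if (any(n < 6))
      stop("malformed BED6 row (fewer than 6 fields) at line ",
           src$lineno[which(n < 6)[1]], call. = FALSE)
    df <- data.frame(
      gene_id = vapply(fl, `[`, "", 4L),
      symbol  = vapply(fl, `[`, "", 4L),
      chrom   = vapply(fl, `[`, "", 1L),
      start   = .as_coord(vapply(fl, `[`, "", 2L), src$lineno, "start"),
      end     = .as_coord(vapply(fl, `[`, "", 3L), src$lineno, "end"),
      strand  = vapply(fl, `[`, "", 6L),
      stringsAsFactors = FALSE)
  } else {
    hdr <- strsplit(src$lines[1], "\t", fixed = TRUE)[[1]]
    need <- c("gene_id", "symbol", "chrom", "start", "end", "strand")
    if (!all(need %in% hdr))
      stop("tsv gene table must have header columns: ",
           paste(need, collapse = ", "), call. = FALSE)
    fl <- .split_fields(src$lines[-1], "\t")
    lineno <- src$lineno[-1]
    n <- lengths(fl)
    if (any(n < length(hdr)))
      stop("malformed row at line ", lineno[which(n < length(hdr))[1]],
           call. = FALSE)
    col <- function(nm) vapply(fl, `[`, "", match(nm, hdr))
    df <- data.frame(
      gene_id = col("gene_id"), symbol = col("symbol"), chrom = col("chrom"),
      start = .as_coord(col("start"), lineno, "start"),
      end   = .as_coord(col("end"), lineno, "end"),
      strand = col("strand"), stringsAsFactors = FALSE)
    src$lineno <- lineno
  }
  .check_intervals(df$start, df$end, src$lineno)
  if (any(!nzchar(df$chrom))) stop("empty chromosome name", call. = FALSE)
  if (!all(df$strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-' at line ",
         src$lineno[which(!df$strand %in% c("+", "-"))[1]], call. = FALSE)
  dup <- duplicated(df$gene_id)
  if (any(dup))
    stop("duplicate gene_id: ", paste(unique(df$gene_id[dup]), collapse = ", "),
         call. = FALSE)
  df$tss <- ifelse(df$strand == "+", df$start, df$end - 1L)
  df
}

#' Read retroelement intervals
#'
#' Dialect `bed6_class_in_name` expects BED6 rows whose name field is
#' `family|class` (e.g. `AluY|SINE`); dialect `repeatmasker_out` parses the
#' RepeatMasker `.out` layout (three header lines skipped, whitespace
#' separated, 1-based inclusive coordinates converted to 0-based half-open,
#' class taken from the repeat class/family column before any `/`).
#'
#' @param path file path.
#' @param dialect `"bed6_class_in_name"` or `"repeatmasker_out"`.
#' @return a `data.frame` with columns `chrom`, `start`, `end`, `strand`,
#'   `name`, `re_class`.
#' @export
read_repeat_table <- function(path,
                              dialect = c("bed6_class_in_name",
                                          "repeatmasker_out")) {
  dialect <- match.arg(dialect)
  if (dialect == "bed6_class_in_name") {
    src <- .read_lines_nocomment(path)
    fl <- .split_fields(src$lines, "ws")
    n <- lengths(fl)
    if (any(n < 6))
      stop("malformed BED6 row at line ", src$lineno[which(n < 6)[1]],
           call. = FALSE)
    nm <- vapply(fl, `[`, "", 4L)
    has_class <- grepl("|", nm, fixed = TRUE)
    cls <- ifelse(has_class, sub("^.*\\|", "", nm), "UNKNOWN")
    df <- data.frame(
      chrom = vapply(fl, `[`, "", 1L),
      start = .as_coord(vapply(fl, `[`, "", 2L), src$lineno, "start"),
      end   = .as_coord(vapply(fl, `[`, "", 3L), src$lineno, "end"),
      strand = vapply(fl, `[`, "", 6L),
      name  = sub("\\|.*$", "", nm),
      re_class = normalize_re_class(cls),
      stringsAsFactors = FALSE)
    .check_intervals(df$start, df$end, src$lineno)
  } else {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    ln <- readLines(path, warn = FALSE)
    if (length(ln) > 3) ln <- ln[-(1:3)] else ln <- character()
    keep <- nzchar(trimws(ln))
    ln <- ln[keep]
    lineno <- which(keep) + 3L
    fl <- .split_fields(ln, "ws")
    n <- lengths(fl)
    if (any(n < 11))
      stop("malformed RepeatMasker row at line ", lineno[which(n < 11)[1]],
           call. = FALSE)
    begin1 <- .as_coord(vapply(fl, `[`, "", 6L), lineno, "begin")
    end1   <- .as_coord(vapply(fl, `[`, "", 7L), lineno, "end")
    df <- data.frame(
      chrom = vapply(fl, `[`, "", 5L),
      start = begin1 - 1L,           # 1-based inclusive -> 0-based half-open
      end   = end1,
      strand = ifelse(vapply(fl, `[`, "", 9L) == "C", "-", "+"),
      name  = vapply(fl, `[`, "", 10L),
      re_class = normalize_re_class(vapply(fl, `[`, "", 11L)),
      stringsAsFactors = FALSE)
    .check_intervals(df$start, df$end, lineno)
  }
  df
}

#' Read histone-tag intervals from a BED file
#'
#' Any interval length is accepted (read-length tags or broad peaks). Tags
#' are returned in file order, each stamped with the mark and cell-line
#' labels supplied by the caller.
#'
#' @param path BED file (3+ columns).
#' @param mark histone mark label (non-empty).
#' @param cell_line cell-line label (non-empty).
#' @return a `data.frame` with columns `chrom`, `start`, `end`, `mark`,
#'   `cell_line`.
#' @export
read_tag_bed <- function(path, mark, cell_line) {
  stopifnot(is.character(mark), nzchar(mark),
            is.character(cell_line), nzchar(cell_line))
  src <- .read_lines_nocomment(path)
  if (!length(src$lines))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), mark = character(),
                      cell_line = character(), stringsAsFactors = FALSE))
  fl <- .split_fields(src$lines, "ws")
  n <- lengths(fl)
  if (any(n < 3))
    stop("malformed BED row at line ", src$lineno[which(n < 3)[1]],
         call. = FALSE)
  df <- data.frame(
    chrom = vapply(fl, `[`, "", 1L),
    start = .as_coord(vapply(fl, `[`, "", 2L), src$lineno, "start"),
    end   = .as_coord(vapply(fl, `[`, "", 3L), src$lineno, "end"),
    mark = mark, cell_line = cell_line, stringsAsFactors = FALSE)
  .check_intervals(df$start, df$end, src$lineno)
  df
}

#' Read gene sets in GMT format
#'
#' Standard GMT: set name, description, then tab-separated gene ids.
#' Duplicate gene ids within one set are deduplicated with a warning; a row
#' with fewer than three fields (i.e. an empty gene set) is an error.
#'
#' @param path GMT file.
#' @param source_label database label recorded on every set.
#' @return a list of pathway definitions, each a list with elements
#'   `pathway_id`, `source`, `description`, `genes` (character vector).
#' @export
read_gmt <- function(path, source_label = "gmt") {
  src <- .read_lines_nocomment(path)
  fl <- .split_fields(src$lines, "\t")
  n <- lengths(fl)
  if (any(n < 3))
    stop("GMT row with fewer than 3 fields at line ",
         src$lineno[which(n < 3)[1]], call. = FALSE)
  out <- vector("list", length(fl))
  for (i in seq_along(fl)) {
    genes <- fl[[i]][-(1:2)]
    genes <- genes[nzchar(genes)]
    if (!length(genes))
      stop("GMT row with empty gene set at line ", src$lineno[i], call. = FALSE)
    if (anyDuplicated(genes)) {
      warning("duplicate gene ids in set '", fl[[i]][1],
              "' deduplicated", call. = FALSE)
      genes <- unique(genes)
    }
    out[[i]] <- list(pathway_id = fl[[i]][1], source = source_label,
                     description = fl[[i]][2], genes = genes)
  }
  names(out) <- vapply(out, `[[`, "", "pathway_id")
  out
}

#' Write a score table as TSV
#'
#' Tab-separated with a header row; missing values are written as `NA`;
#' numeric columns are written with 17 significant digits so a read-back
#' round-trips every double bit-exactly. Optional `#`-prefixed header
#' comment lines carry provenance (seed, config hash).
#'
#' @param records a `data.frame` with a uniform column set.
#' @param path output path.
#' @param comment character vector of comment lines (without leading `#`).
#' @export
write_scores_tsv <- function(records, path, comment = NULL) {
  stopifnot(is.data.frame(records))
  out <- records
  for (j in seq_along(out))
    if (is.double(out[[j]]))
      out[[j]] <- ifelse(is.na(out[[j]]), NA,
                         formatC(out[[j]], digits = 17, format = "g"))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, na = "NA",
                     row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_scores_tsv()]
#'
#' @param path input path.
#' @return a `data.frame`; columns that parse as numbers become numeric.
#' @export
read_scores_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", sep = "\t",
                    stringsAsFactors = FALSE, na.strings = "NA",
                    check.names = FALSE)
}

#' Write intervals as BED6
#'
#' @param df data.frame with `chrom`, `start`, `end` and optionally `name`,
#'   `score`, `strand`.
#' @param path output path.
#' @param comment header comment lines (without leading `#`).
#' @export
write_bed <- function(df, path, comment = NULL) {
  nm <- if ("name" %in% names(df)) df$name else "."
  sc <- if ("score" %in% names(df)) df$score else 0L
  st <- if ("strand" %in% names(df)) df$strand else "."
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comment)) writeLines(paste0("# ", comment), con)
  writeLines(paste(df$chrom, df$start, df$end, nm, sc, st, sep = "\t"), con)
  invisible(path)
}

#' Write gene sets in GMT format
#'
#' @param sets list as returned by [read_gmt()].
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  ln <- vapply(sets, function(s)
    paste(c(s$pathway_id, s$description, s$genes), collapse = "\t"), "")
  writeLines(ln, path)
  invisible(path)
}
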