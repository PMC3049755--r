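#' Read a 12-column tabular alignment hit table
#'
#' Parses the standard 12-column tab-separated local-alignment format (query,
#' subject, percent identity, alignment length, mismatches, gap opens, qstart,
#' qend, sstart, send, e-value, bit score; printed coordinates 1-based
#' inclusive). Coordinates are normalised to 0-based half-open offsets on the
#' query's coordinate system (peptide residues for peptide searches, CDS
#' nucleotides for nucleotide searches); subject coordinate order encodes
#' orientation (`sstart > send` means inverted) and is normalised to
#' `s_start < s_end` plus an `orientation` column.
#'
#' @param tabular_source path to the hit table (no header).
#' @param query_kind `"peptide"` or `"nucleotide"`; stored on the result.
#' @param strict if `TRUE` (default) a malformed row is an error naming the
#'   line; if `FALSE` malformed rows are skipped with a warning.
#' @return data.frame of HSPs with columns `query_id`, `subject_id`,
#'   `percent_identity`, `n_columns`, `mismatches`, `gap_opens`, `q_start`,
#'   `q_end`, `s_start`, `s_end`, `orientation`, `e_value`, `score` and
#'   attribute `query_kind`.
#' @export
readHitTable <- function(tabular_source, query_kind = c("nucleotide",
                                                        "peptide"),
                         strict = TRUE) {
    query_kind <- match.arg(query_kind)
    raw <- readLines(tabular_source)
    raw <- raw[nzchar(raw) & !startsWith(raw, "#")]
    if (!length(raw)) {
        out <- emptyHitTable()
        attr(out, "query_kind") <- query_kind
        return(out)
    }
    parts <- strsplit(raw, "\t", fixed = TRUE)
    rows <- vector("list", length(parts))
    bad <- character()
    for (i in seq_along(parts)) {
        p <- parts[[i]]
        row <- tryCatch(parseHitRow(p), error = function(e) e)
        if (inherits(row, "error")) {
            msg <- sprintf("line %d: %s", i, conditionMessage(row))
            if (strict) stop("malformed hit-table row at ", msg)
            bad <- c(bad, msg)
        } else rows[[i]] <- row
    }
    if (length(bad))
        warning("skipped ", length(bad), " malformed row(s): ",
                paste(bad, collapse = "; "))
    out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    if (is.null(out)) out <- emptyHitTable()
    rownames(out) <- NULL
    attr(out, "query_kind") <- query_kind
    out
}

parseHitRow <- function(p) {
    if (length(p) != 12L) stop("expected 12 tab-separated columns, got ",
                               length(p))
    num <- suppressWarnings(as.numeric(p[c(3:11, 12)]))
    if (anyNA(num)) stop("non-numeric value in numeric column")
    qs <- as.integer(num[5]); qe <- as.integer(num[6])
    ss <- as.integer(num[7]); se <- as.integer(num[8])
    ev <- num[9]
    if (qs > qe) stop("reversed query coordinates")
    if (ev < 0) stop("negative e-value")
    inverted <- ss > se
    data.frame(query_id = p[1], subject_id = p[2],
               percent_identity = num[1],
               n_columns = as.integer(num[2]),
               mismatches = as.integer(num[3]),
               gap_opens = as.integer(num[4]),
               q_start = qs - 1L, q_end = qe,
               s_start = if (inverted) se - 1L else ss - 1L,
               s_end = if (inverted) ss else se,
               orientation = if (inverted) "inverted" else "forward",
               e_value = ev, score = num[10],
               stringsAsFactors = FALSE)
}

emptyHitTable <- function() {
    data.frame(query_id = character(), subject_id = character(),
               percent_identity = numeric(), n_columns = integer(),
               mismatches = integer(), gap_opens = integer(),
               q_start = integer(), q_end = integer(),
               s_start = integer(), s_end = integer(),
               orientation = character(), e_value = numeric(),
               score = numeric(), stringsAsFactors = FALSE)
}

#' Write HSPs in 12-column tabular format
#'
#' Inverse of [readHitTable()]: converts back to 1-based inclusive printed
#' coordinates, encoding inverted orientation as `sstart > send`.
#'
#' @param hsps HSP data.frame as produced by [readHitTable()] or
#'   [toySearch()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeHitTable <- function(hsps, path) {
    lines <- character(nrow(hsps))
    for (i in seq_len(nrow(hsps))) {
        h <- hsps[i, ]
        inv <- h$orientation == "inverted"
        lines[i] <- paste(h$query_id, h$subject_id,
                          sprintf("%.2f", h$percent_identity),
                          h$n_columns, h$mismatches, h$gap_opens,
                          h$q_start + 1L, h$q_end,
                          if (inv) h$s_end else h$s_start + 1L,
                          if (inv) h$s_start + 1L else h$s_end,
                          formatC(h$e_value, format = "e", digits = 2),
                          sprintf("%.1f", h$score), sep = "\t")
    }
    writeLines(lines, path, sep = "\n")
    invisible(path)
}
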