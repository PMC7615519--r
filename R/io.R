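# Readers and writers for p-value streams and decision logs, plus the
# packaged platform-trial fixture. CSV throughout; numeric columns are
# written with %.17g so that read(write(x)) round-trips bit-exactly.
# Output files carry `#` comment headers recording the package version and
# run configuration, and a footer with the next-hypothesis level.

fmt_num <- function(x) sprintf("%.17g", x)

#' Read a p-value stream
#'
#' Expects a CSV with header `id,pval[,batch]`; row order is preserved
#' exactly as on disk. Lines starting with `#` are ignored.
#'
#' @param path file path.
#' @return a data frame with columns `id`, `pval` and (if present) `batch`,
#'   class `"pvalue_stream"`.
#' @export
read_stream <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("stream file has no header")
  header <- trimws(strsplit(lines[1], ",")[[1]])
  if (length(header) < 2 || header[1] != "id" || header[2] != "pval") {
    stop("stream file must have header 'id,pval[,batch]'")
  }
  has_batch <- length(header) >= 3 && header[3] == "batch"
  n <- length(lines) - 1L
  id <- character(n); pval <- numeric(n)
  batch <- if (has_batch) character(n) else NULL
  for (i in seq_len(n)) {
    ln <- lineno[i + 1L]
    parts <- strsplit(lines[i + 1L], ",")[[1]]
    if (length(parts) < 2) {
      stop(sprintf("malformed row at line %d", ln))
    }
    pv <- suppressWarnings(as.numeric(parts[2]))
    if (is.na(pv)) stop(sprintf("malformed p-value at line %d", ln))
    if (pv < 0 || pv > 1) {
      stop(sprintf("p-value out of [0, 1] at line %d: %s", ln, parts[2]))
    }
    id[i] <- trimws(parts[1]); pval[i] <- pv
    if (has_batch) batch[i] <- if (length(parts) >= 3) trimws(parts[3]) else ""
  }
  if (anyDuplicated(id)) stop("stream ids must be unique")
  out <- data.frame(id = id, pval = pval, stringsAsFactors = FALSE)
  if (has_batch) out$batch <- batch
  structure(out, class = c("pvalue_stream", "data.frame"))
}

#' Write a p-value stream
#'
#' @param stream a data frame with columns `id`, `pval` and optionally
#'   `batch`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_stream <- function(stream, path) {
  has_batch <- "batch" %in% names(stream)
  header <- if (has_batch) "id,pval,batch" else "id,pval"
  rows <- if (nrow(stream) == 0) character(0) else {
    r <- paste0(stream$id, ",", fmt_num(stream$pval))
    if (has_batch) paste0(r, ",", stream$batch) else r
  }
  ok <- tryCatch({
    writeLines(c(header, rows), path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop(sprintf("cannot write to %s", path))
  invisible(path)
}

#' The packaged STAMPEDE platform-trial p-values
#'
#' Seven reported treatment-versus-control p-values from the STAMPEDE
#' prostate-cancer platform trial, in arrival order B, C, E, D, F, G, H
#' (alphabetical within each of the four arrival batches). The `batch`
#' column records which hypotheses became testable together.
#'
#' @return a `pvalue_stream` with 7 rows.
#' @examples
#' run_stream(stampede_fixture()$pval, saffron(bound = 20),
#'            ids = stampede_fixture()$id)
#' @export
stampede_fixture <- function() {
  read_stream(system.file("extdata", "stampede_pvalues.csv",
                          package = "alphastream", mustWork = TRUE))
}

#' Write / read a decision log
#'
#' The CSV carries comment headers (`#`) with the package version and the
#' policy configuration, the columns `index,id,pval,alpha,reject,wealth`
#' (numerics at full `%.17g` precision so round-trips are bit-exact), and a
#' footer comment with the next-hypothesis level at full precision and
#' rounded to 4 decimals (round-half-even).
#'
#' @param log a `decision_log` from [run_stream()].
#' @param path destination file.
#' @param extra named character vector of extra header fields (e.g. seed).
#' @return `write_decision_log()` returns `path` invisibly;
#'   `read_decision_log()` returns a data frame with the logged columns and
#'   attribute `next_level` (if present in the file).
#' @export
write_decision_log <- function(log, path, extra = NULL) {
  pol <- attr(log, "policy")
  hdr <- c(sprintf("# alphastream %s", as.character(packageVersion("alphastream"))),
           if (!is.null(pol)) {
             pars <- pol[setdiff(names(pol), c("name", "gamma"))]
             pars <- pars[!vapply(pars, is.null, logical(1))]
             sprintf("# policy: %s (%s)", pol$name,
                     paste(names(pars), unlist(pars), sep = "=", collapse = ", "))
           },
           if (!is.null(extra)) sprintf("# %s: %s", names(extra), extra))
  has_batch <- "batch" %in% names(log)
  cols <- "index,id,pval,alpha,reject,wealth"
  if (has_batch) cols <- paste0(cols, ",batch")
  rows <- if (nrow(log) == 0) character(0) else {
    r <- paste0(log$index, ",", log$id, ",", fmt_num(log$pval), ",",
                fmt_num(log$alpha), ",", log$reject, ",",
                fmt_num(log$wealth))
    if (has_batch) paste0(r, ",", log$batch) else r
  }
  nl <- next_level(log)
  ftr <- if (!is.null(nl)) {
    sprintf("# next_level: %s (rounded: %.4f)", fmt_num(nl), round(nl, 4))
  }
  ok <- tryCatch({
    writeLines(c(hdr, cols, rows, ftr), path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop(sprintf("cannot write to %s", path))
  invisible(path)
}

#' @rdname write_decision_log
#' @export
read_decision_log <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path)
  nl_line <- grep("^# next_level:", lines, value = TRUE)
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(body)) stop("decision log has no header")
  header <- strsplit(body[1], ",")[[1]]
  need <- c("index", "id", "pval", "alpha", "reject", "wealth")
  if (!all(need == header[seq_along(need)])) {
    stop("decision log must have columns index,id,pval,alpha,reject,wealth")
  }
  n <- length(body) - 1L
  parts <- strsplit(body[-1], ",")
  get <- function(k) vapply(parts, `[[`, character(1), k)
  out <- data.frame(index = as.integer(get(1)), id = get(2),
                    pval = as.numeric(get(3)), alpha = as.numeric(get(4)),
                    reject = as.integer(get(5)), wealth = as.numeric(get(6)),
                    stringsAsFactors = FALSE)
  if (length(header) >= 7 && header[7] == "batch") out$batch <- get(7)
  if (length(nl_line)) {
    attr(out, "next_level") <-
      as.numeric(sub("^# next_level: (\\S+).*$", "\\1", nl_line[1]))
  }
  out
}

#' Write a results table
#'
#' Plain CSV with a version comment header; used for [run_experiment()]
#' output.
#'
#' @param table a data frame.
#' @param path destination file.
#' @param extra named character vector of extra header fields.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path, extra = NULL) {
  con <- tryCatch(file(path, "w"), error = function(e) NULL,
                  warning = function(w) NULL)
  if (is.null(con)) stop(sprintf("cannot write to %s", path))
  on.exit(close(con))
  writeLines(c(sprintf("# alphastream %s",
                       as.character(packageVersion("alphastream"))),
               if (!is.null(extra)) sprintf("# %s: %s", names(extra), extra)),
             con)
  write.csv(table, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
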