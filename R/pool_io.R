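# Delimited-text pool format: one row per signal with columns
# subject_id, task_label, subphase_spec, tr_seconds, s0..s{T-1}.
# subphase_spec serialises the design annotation as semicolon-separated
# label:start:end triples (1-based inclusive sample indices), or "" for none.
# Signals shorter than the widest row are stored with trailing empty cells.

format_design <- function(design) {
  if (is.null(design) || nrow(design) == 0L) return("")
  paste(sprintf("%s:%d:%d", design$label, design$start, design$end),
        collapse = ";")
}

parse_design <- function(spec, n, line) {
  if (is.na(spec) || !nzchar(spec)) return(NULL)
  parts <- strsplit(strsplit(spec, ";", fixed = TRUE)[[1L]], ":", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 3L
  if (any(bad))
    stopf("line %d: malformed subphase_spec triple '%s'", line,
          paste(parts[[which(bad)[1L]]], collapse = ":"))
  design <- data.frame(
    label = vapply(parts, `[`, "", 1L),
    start = suppressWarnings(as.integer(vapply(parts, `[`, "", 2L))),
    end = suppressWarnings(as.integer(vapply(parts, `[`, "", 3L))),
    stringsAsFactors = FALSE)
  if (anyNA(design$start) || anyNA(design$end))
    stopf("line %d: non-integer block boundary in subphase_spec", line)
  tryCatch(validate_design(design, n),
           error = function(e) stopf("line %d: %s", line, conditionMessage(e)))
}

#' Write a signal pool to delimited text
#'
#' @param pool A [signal_pool()].
#' @param path Output file path (CSV, UTF-8, '.' decimal separator). Doubles
#'   are written with shortest round-trip precision so that
#'   [load_pool()] recovers them bit-exactly.
#' @return `path`, invisibly.
#' @export
save_pool <- function(pool, path) {
  stopifnot(inherits(pool, "signal_pool"))
  lens <- vapply(pool$signals, function(s) length(s$values), 1L)
  width <- max(lens)
  rows <- lapply(pool$signals, function(s) {
    v <- s$values
    length(v) <- width                    # NA-fill short signals
    # %.17g guarantees a bit-exact double round-trip through text
    vs <- ifelse(is.na(v), NA_character_, sprintf("%.17g", v))
    c(list(subject_id = s$subject_id, task_label = s$task_label,
           subphase_spec = format_design(s$design),
           tr_seconds = sprintf("%.17g", s$tr_seconds)),
      as.list(vs))
  })
  dt <- data.table::rbindlist(rows)
  data.table::setnames(dt, c("subject_id", "task_label", "subphase_spec",
                             "tr_seconds", paste0("s", seq_len(width) - 1L)))
  data.table::fwrite(dt, path, na = "")
  invisible(path)
}

#' Read a signal pool from delimited text
#'
#' Parses the pool format written by [save_pool()] (and by the synthetic
#' generator's command-line interface). Malformed headers, non-numeric
#' samples, or inconsistent rows raise an error naming the offending line.
#'
#' @param path Path to a pool CSV file.
#' @param format Only `"csv"` is supported.
#' @param target_length Post-padding length recorded on the returned pool
#'   (default 600).
#' @return A [signal_pool()].
#' @export
load_pool <- function(path, format = c("csv"), target_length = 600L) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("pool file '%s' does not exist", path)
  dt <- tryCatch(
    data.table::fread(path, sep = ",", header = TRUE, na.strings = "",
                      colClasses = list(character = c(1L, 2L, 3L))),
    error = function(e) stopf("failed to parse '%s': %s", path,
                              conditionMessage(e)))
  required <- c("subject_id", "task_label", "subphase_spec", "tr_seconds")
  missing <- setdiff(required, names(dt))
  if (length(missing))
    stopf("line 1: pool header lacks column(s): %s",
          paste(missing, collapse = ", "))
  scols <- grep("^s[0-9]+$", names(dt), value = TRUE)
  if (!length(scols)) stopf("line 1: pool header has no sample columns s0..")
  scols <- scols[order(as.integer(sub("^s", "", scols)))]
  vals <- as.matrix(dt[, scols, with = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(apply(vals, 1L, function(r)
      anyNA(suppressWarnings(as.numeric(r[r != "" & !is.na(r)])))))[1L]
    stopf("line %d: non-numeric sample value", bad + 1L)
  }
  signals <- lapply(seq_len(nrow(dt)), function(i) {
    v <- vals[i, ]
    keep <- rev(cumsum(rev(!is.na(v)))) > 0   # strip trailing NA fill only
    v <- v[keep]
    if (anyNA(v)) stopf("line %d: missing sample inside signal", i + 1L)
    if (!length(v)) stopf("line %d: empty signal row", i + 1L)
    bold_signal(v, tr_seconds = dt$tr_seconds[i],
                task_label = dt$task_label[i], subject_id = dt$subject_id[i],
                design = parse_design(dt$subphase_spec[i], length(v), i + 1L))
  })
  signal_pool(signals, target_length = target_length,
              provenance = paste0("loaded from ", path))
}
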