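## Minimal FCS 3.0/3.1 list-mode support. Deliberately narrow: float, double
## or fixed-width integer data, one dataset per file, $PnE log amplification
## and $PnG gain decoded so values come back on the linear scale. Anything
## else is rejected loudly rather than guessed.

fcs_parse_text <- function(raw_text) {
  txt <- rawToChar(raw_text)
  delim <- substr(txt, 1, 1)
  parts <- strsplit(substring(txt, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  keys <- toupper(trimws(parts[seq(1, length(parts), 2)]))
  vals <- trimws(parts[seq(2, length(parts), 2)])
  stats::setNames(vals, keys)
}

#' Read a flow cytometry standard (FCS) file
#'
#' Reads FCS 3.0/3.1 list-mode data. Channel names are taken from the `$PnN`
#' short names, falling back to `$PnS` stain names. `$PnE` log amplification
#' (`value = f2 * 10^(f1 * x / $PnR)`) and `$PnG` linear gain are applied so
#' the returned intensities are on the linear scale.
#'
#' @param path path to an FCS file.
#' @return an [event_matrix()] with `scale = "linear"`.
#' @export
read_fcs <- function(path) {
  if (!file.exists(path)) cc_stop(paste0("no such file: ", path), "cc_format_error")
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  header <- readBin(con, "raw", 58L)
  if (length(header) < 58L) cc_stop("file too short for an FCS header", "cc_format_error")
  version <- rawToChar(header[1:6])
  if (!version %in% c("FCS3.0", "FCS3.1"))
    cc_stop(paste0("unsupported FCS version: ", version), "cc_format_error")
  offs <- vapply(0:5, function(i) {
    s <- trimws(rawToChar(header[(11 + 8 * i):(18 + 8 * i)]))
    if (s == "") 0 else suppressWarnings(as.numeric(s))
  }, numeric(1))
  if (anyNA(offs)) cc_stop("unparseable FCS header offsets", "cc_format_error")
  seek(con, offs[1])
  kw <- fcs_parse_text(readBin(con, "raw", offs[2] - offs[1] + 1))

  need <- function(k) {
    if (is.na(kw[k]) || !nzchar(kw[k]))
      cc_stop(paste0("missing required FCS keyword ", k), "cc_format_error")
    kw[[k]]
  }
  if (!is.na(kw["$NEXTDATA"]) && as.numeric(kw["$NEXTDATA"]) != 0)
    warning("FCS file contains additional datasets; only the first is read")
  if (need("$MODE") != "L")
    cc_stop("only list-mode ($MODE L) FCS is supported", "cc_format_error")
  dtype <- need("$DATATYPE")
  if (!dtype %in% c("F", "D", "I"))
    cc_stop(paste0("unsupported $DATATYPE ", dtype), "cc_format_error")
  byteord <- need("$BYTEORD")
  endian <- if (byteord %in% c("1,2,3,4", "1,2")) "little"
            else if (byteord %in% c("4,3,2,1", "2,1")) "big"
            else cc_stop(paste0("unsupported $BYTEORD ", byteord), "cc_format_error")
  p <- as.integer(need("$PAR"))
  tot <- as.integer(need("$TOT"))

  data_beg <- offs[3]; data_end <- offs[4]
  if (data_beg == 0 || data_end == 0) {
    data_beg <- as.numeric(need("$BEGINDATA"))
    data_end <- as.numeric(need("$ENDDATA"))
  }
  bits <- vapply(seq_len(p), function(i) as.integer(need(paste0("$P", i, "B"))), integer(1))
  if (dtype == "F" && any(bits != 32L))
    cc_stop("float data requires 32-bit parameters", "cc_format_error")
  if (dtype == "D" && any(bits != 64L))
    cc_stop("double data requires 64-bit parameters", "cc_format_error")
  if (dtype == "I" && (length(unique(bits)) != 1L || !bits[1] %in% c(16L, 32L)))
    cc_stop("integer data requires uniform 16- or 32-bit parameters", "cc_format_error")

  seek(con, data_beg)
  nvals <- p * tot
  values <- switch(dtype,
    F = readBin(con, "numeric", nvals, size = 4, endian = endian),
    D = readBin(con, "numeric", nvals, size = 8, endian = endian),
    I = readBin(con, "integer", nvals, size = bits[1] / 8, signed = bits[1] > 16,
                endian = endian))
  if (length(values) < nvals)
    cc_stop("FCS data segment shorter than $PAR * $TOT", "cc_format_error")
  m <- matrix(values, nrow = tot, ncol = p, byrow = TRUE)

  nm <- character(p)
  for (i in seq_len(p)) {
    n1 <- kw[paste0("$P", i, "N")]; n2 <- kw[paste0("$P", i, "S")]
    nm[i] <- if (!is.na(n1) && nzchar(n1)) n1
             else if (!is.na(n2) && nzchar(n2)) n2
             else paste0("P", i)
  }
  if (anyDuplicated(nm)) cc_stop("duplicate channel names in FCS file", "cc_panel_error")

  ## decode amplification/gain to linear scale
  for (i in seq_len(p)) {
    pne <- kw[paste0("$P", i, "E")]
    f <- if (!is.na(pne) && nzchar(pne)) as.numeric(strsplit(pne, ",")[[1]]) else c(0, 0)
    if (length(f) == 2 && !anyNA(f) && f[1] > 0) {
      pnr <- kw[paste0("$P", i, "R")]
      if (is.na(pnr)) cc_stop("$PnE log amplification requires $PnR", "cc_format_error")
      f2 <- if (f[2] == 0) 1 else f[2]
      m[, i] <- f2 * 10^(f[1] * m[, i] / as.numeric(pnr))
    } else {
      png <- kw[paste0("$P", i, "G")]
      if (!is.na(png) && nzchar(png)) {
        g <- as.numeric(png)
        if (is.finite(g) && g > 0 && g != 1) m[, i] <- m[, i] / g
      }
    }
  }
  event_matrix(m, channel_panel(nm), scale = "linear")
}

#' Write a minimal FCS 3.0 fixture file
#'
#' Fixture writer used for round-trip tests and small exports: single
#' dataset, list mode, 32-bit float, little endian. `pne`, `png` and `pnr`
#' allow writing amplification/gain keywords so reader semantics can be
#' exercised; in that case `values` are written as raw machine values.
#'
#' @param m an [event_matrix()].
#' @param path output path.
#' @param pne,png,pnr optional per-channel `$PnE`, `$PnG`, `$PnR` keyword
#'   values (character/numeric vectors).
#' @return `path`, invisibly.
#' @export
write_fcs <- function(m, path, pne = NULL, png = NULL, pnr = NULL) {
  v <- m$values
  p <- ncol(v); tot <- nrow(v)
  kw <- c("$DATATYPE" = "F", "$MODE" = "L", "$BYTEORD" = "1,2,3,4",
          "$PAR" = as.character(p), "$TOT" = as.character(tot),
          "$NEXTDATA" = "0",
          "$BEGINDATA" = sprintf("%010d", 0), "$ENDDATA" = sprintf("%010d", 0))
  for (i in seq_len(p)) {
    kw[paste0("$P", i, "N")] <- colnames(v)[i]
    kw[paste0("$P", i, "B")] <- "32"
    kw[paste0("$P", i, "E")] <- if (!is.null(pne)) as.character(pne[i]) else "0,0"
    kw[paste0("$P", i, "R")] <- if (!is.null(pnr)) as.character(pnr[i]) else
      format(max(1024, ceiling(max(v[, i], 1))), scientific = FALSE)
    if (!is.null(png)) kw[paste0("$P", i, "G")] <- as.character(png[i])
  }
  build <- function(kw) paste0("/", paste(names(kw), kw, sep = "/", collapse = "/"), "/")
  txt <- build(kw)
  text_beg <- 58L
  text_end <- text_beg + nchar(txt, type = "bytes") - 1L
  data_beg <- text_end + 1L
  data_end <- data_beg + 4L * p * tot - 1L
  kw["$BEGINDATA"] <- sprintf("%010d", data_beg)
  kw["$ENDDATA"] <- sprintf("%010d", data_end)
  txt <- build(kw)  # same byte length: offsets fixed width
  header <- sprintf("FCS3.0    %8d%8d%8d%8d%8d%8d",
                    text_beg, text_end, data_beg, data_end, 0L, 0L)
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeChar(header, con, eos = NULL)
  writeChar(txt, con, eos = NULL)
  writeBin(as.vector(t(v)), con, size = 4, endian = "little")
  invisible(path)
}
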