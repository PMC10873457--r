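# File I/O: lenient molecule readers. Chemically invalid records are the
# tool's intended inputs, so only *syntactic* failures are rejected -- and
# per record, never with a crash.

#' Read molecules from a SMILES or SDF file
#'
#' Syntactically valid records parse without any valence check. Ill-formed
#' records do not abort the read: they are skipped and reported in the
#' `errors` attribute (a data.frame with `line`/`record`, `text` and
#' `message` columns).
#'
#' @param path input file. `.smi` files hold one SMILES per line with an
#'   optional whitespace-separated name; `.sdf` files are V2000 molfiles.
#' @param format `"smi"`, `"sdf"`, or `"auto"` (from the file extension).
#' @return A named list of [molgraph]s with attribute `errors`.
#' @export
read_molecules <- function(path, format = c("auto", "smi", "sdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read '", path, "'")
  if (format == "auto")
    format <- if (grepl("\\.sdf$", path, ignore.case = TRUE)) "sdf" else "smi"
  if (format == "smi") read_smi_file(path) else read_sdf_file(path)
}

read_smi_file <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  mols <- list()
  errs <- data.frame(line = integer(0), text = character(0),
                     message = character(0))
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    fld <- strsplit(ln, "[ \t]+")[[1L]]
    m <- tryCatch(parse_smiles(fld[1L]), error = function(e) e)
    if (inherits(m, "error")) {
      errs <- rbind(errs, data.frame(line = i, text = ln,
                                     message = conditionMessage(m)))
    } else {
      nm <- if (length(fld) >= 2L) fld[2L] else sprintf("mol%05d", i)
      mols[[nm]] <- m
    }
  }
  attr(mols, "errors") <- errs
  mols
}

read_sdf_file <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  breaks <- c(0L, which(trimws(lines) == "$$$$"))
  mols <- list()
  errs <- data.frame(line = integer(0), text = character(0),
                     message = character(0))
  for (r in seq_len(length(breaks) - 1L)) {
    rec <- lines[(breaks[r] + 1L):(breaks[r + 1L] - 1L)]
    if (all(!nzchar(trimws(rec)))) next
    m <- tryCatch(parse_sdf_record(rec), error = function(e) e)
    if (inherits(m, "error")) {
      errs <- rbind(errs, data.frame(line = breaks[r] + 1L,
                                     text = if (length(rec) > 0L) rec[1L] else "",
                                     message = conditionMessage(m)))
    } else {
      nm <- trimws(rec[1L])
      if (!nzchar(nm)) nm <- sprintf("mol%05d", r)
      mols[[nm]] <- m
    }
  }
  attr(mols, "errors") <- errs
  mols
}

# V2000 molfile body (without the terminating $$$$)
parse_sdf_record <- function(rec) {
  if (length(rec) < 4L) stop("truncated molfile record")
  counts <- rec[4L]
  na <- suppressWarnings(as.integer(substr(counts, 1L, 3L)))
  nb <- suppressWarnings(as.integer(substr(counts, 4L, 6L)))
  if (is.na(na) || is.na(nb)) stop("malformed counts line")
  if (length(rec) < 4L + na + nb) stop("truncated atom/bond block")
  Z <- integer(na); Q <- integer(na)
  old_charge <- c(`1` = 3L, `2` = 2L, `3` = 1L, `5` = -1L, `6` = -2L, `7` = -3L)
  for (i in seq_len(na)) {
    fld <- strsplit(trimws(rec[4L + i]), "[ \t]+")[[1L]]
    if (length(fld) < 4L) stop("malformed atom line ", i)
    Z[i] <- symbol_to_Z(fld[4L])
    if (length(fld) >= 6L) {
      cc <- old_charge[fld[6L]]
      if (!is.na(cc)) Q[i] <- cc
    }
  }
  ba <- integer(nb); bb <- integer(nb); border <- integer(nb)
  for (i in seq_len(nb)) {
    bl <- rec[4L + na + i]
    fld <- strsplit(trimws(bl), "[ \t]+")[[1L]]
    if (length(fld) < 3L) stop("malformed bond line ", i)
    ba[i] <- as.integer(fld[1L]); bb[i] <- as.integer(fld[2L])
    border[i] <- as.integer(fld[3L])
    if (is.na(ba[i]) || is.na(bb[i]) || is.na(border[i]))
      stop("malformed bond line ", i)
  }
  # property block: M CHG overrides all charges
  for (ln in rec[-seq_len(4L + na + nb)]) {
    if (startsWith(ln, "M  CHG")) {
      fld <- as.integer(strsplit(trimws(substring(ln, 7L)), "[ \t]+")[[1L]])
      k <- fld[1L]
      Q[] <- 0L
      for (j in seq_len(k)) Q[fld[2L * j]] <- fld[2L * j + 1L]
    }
  }
  arom <- rep(FALSE, na)
  bsym <- character(nb)
  for (i in seq_len(nb)) {
    if (border[i] == 4L) {
      bsym[i] <- ":"
      arom[ba[i]] <- TRUE; arom[bb[i]] <- TRUE
    } else if (border[i] %in% 1:3) {
      bsym[i] <- c("-", "=", "#")[border[i]]
    } else stop("unsupported bond order ", border[i], " in bond line ", i)
  }
  finalize_parsed(Z, Q, rep(NA_integer_, na), arom, ba, bb, bsym)
}

#' Write molecules to a SMILES file
#'
#' @param mols a list of [molgraph]s (names become record ids).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_smiles_file <- function(mols, path) {
  smi <- vapply(mols, write_smiles, character(1L))
  ids <- names(mols)
  lines <- if (is.null(ids)) smi else paste(smi, ids, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
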