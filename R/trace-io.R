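#' Column dialect for delimited trace files
#'
#' Test-machine exports vary in column naming and delimiter; a dialect names
#' the mapping explicitly rather than sniffing it.
#'
#' @param sep field delimiter.
#' @param time,force,extension column names holding time (s), force (N) and
#'   extension (mm).
#' @param comment comment prefix for header lines.
#' @return a named list consumed by [readTrace()] / [writeTrace()].
#' @export
traceDialect <- function(sep = "\t", time = "time_s", force = "force_N",
                         extension = "extension_mm", comment = "#") {
  list(sep = sep, time = time, force = force, extension = extension,
       comment = comment)
}

#' Read a force-extension trace from a delimited text file
#'
#' Parses and validates a sampled test record.  Numeric parsing is
#' locale-independent (decimal point) and whitespace-tolerant; the sample
#' rate is inferred from the time column.
#'
#' @param path file path.
#' @param dialect a [traceDialect()] naming columns and delimiter.
#' @return a [ForceExtensionTrace-class].
#' @export
readTrace <- function(path, dialect = traceDialect()) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  df <- read.table(path, header = TRUE, sep = dialect$sep,
                   comment.char = dialect$comment, strip.white = TRUE,
                   check.names = FALSE)
  need <- c(dialect$time, dialect$force, dialect$extension)
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("format error: missing columns ", paste(miss, collapse = ", "))
  tt <- as.numeric(df[[dialect$time]])
  ff <- as.numeric(df[[dialect$force]])
  xx <- as.numeric(df[[dialect$extension]])
  dtt <- diff(tt)
  if (any(dtt == 0))
    stop("data error: duplicated timestamp at row ", which(dtt == 0)[1] + 1L)
  if (any(dtt < 0))
    stop("data error: non-monotone time at row ", which(dtt < 0)[1] + 1L)
  if (any(!is.finite(ff)))
    stop("data error: missing/non-finite force at rows ",
         paste(head(which(!is.finite(ff)), 10), collapse = ", "))
  ForceExtensionTrace(tt, ff, xx)
}

#' Write a force-extension trace to a delimited text file
#'
#' Header comment lines (`# key: value`) record provenance such as the
#' generator seed; the body holds one row per sample.
#'
#' @param trace a [ForceExtensionTrace-class].
#' @param path output file path.
#' @param meta named list written into the comment header.
#' @param dialect a [traceDialect()].
#' @return `path`, invisibly.
#' @export
writeTrace <- function(trace, path, meta = list(), dialect = traceDialect()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("%s %s: %s", dialect$comment, k, format(meta[[k]])), con)
  df <- data.frame(t = sprintf("%.10g", trace@time),
                   f = sprintf("%.10g", trace@force),
                   x = sprintf("%.10g", trace@extension))
  colnames(df) <- c(dialect$time, dialect$force, dialect$extension)
  write.table(df, con, sep = dialect$sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a specimen metadata sheet
#'
#' One row per tested specimen: `specimen_id`, `animal_id`, `age_group`
#' (foetus, 0 days, 0-1 month, 3-6 months, 1-2 years), `tendon` (SDFT/CDET),
#' `phase` (fascicle/IFM), `gauge_length` (mm), `diameters` (fascicles:
#' semicolon-separated mm), `ifm_length` (IFM: mm, nominally 10).
#'
#' @param meta data frame.
#' @return the validated data frame (diameters parsed into a list column
#'   `diameter_list`).
#' @export
validateSpecimenSheet <- function(meta) {
  need <- c("specimen_id", "animal_id", "age_group", "tendon", "phase",
            "gauge_length")
  miss <- setdiff(need, colnames(meta))
  if (length(miss))
    stop("metadata sheet missing columns: ", paste(miss, collapse = ", "))
  if (!all(meta$age_group %in% AGE_GROUPS))
    stop("unknown age_group values: ",
         paste(unique(setdiff(meta$age_group, AGE_GROUPS)), collapse = ", "))
  if (!all(meta$tendon %in% TENDONS)) stop("tendon must be SDFT or CDET")
  if (!all(meta$phase %in% PHASES)) stop("phase must be fascicle or IFM")
  if (any(meta$gauge_length <= 0)) stop("gauge_length must be > 0")
  meta$diameter_list <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    if (meta$phase[i] == "fascicle") {
      d <- suppressWarnings(as.numeric(strsplit(
        as.character(meta$diameters[i]), ";")[[1]]))
      if (!length(d) || any(!is.finite(d)) || any(d <= 0))
        stop("specimen ", meta$specimen_id[i],
             ": fascicle rows need positive diameters")
      meta$diameter_list[[i]] <- d
    } else {
      if (is.null(meta$ifm_length) || !is.finite(meta$ifm_length[i]) ||
          meta$ifm_length[i] <= 0)
        stop("specimen ", meta$specimen_id[i], ": IFM rows need ifm_length > 0")
    }
  }
  meta
}

#' Read/write the specimen metadata sheet
#'
#' @param path delimited text file, one row per specimen.
#' @param sep field delimiter.
#' @return `readSpecimenSheet`: validated data frame.
#' @seealso [validateSpecimenSheet()] for the required columns.
#' @export
readSpecimenSheet <- function(path, sep = "\t") {
  validateSpecimenSheet(read.table(path, header = TRUE, sep = sep,
                                   comment.char = "#", strip.white = TRUE,
                                   check.names = FALSE))
}

#' @rdname readSpecimenSheet
#' @param meta specimen data frame (list columns are flattened).
#' @export
writeSpecimenSheet <- function(meta, path, sep = "\t") {
  meta$diameter_list <- NULL
  write.table(meta, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Label protocol segments of a trace
#'
#' Assigns each sample to `preload`, `preconditioning` or `ramp`.  The
#' terminal ramp is found as the maximal non-decreasing suffix of the
#' commanded extension; preconditioning cycles are detected by
#' zero-crossings of the band-centred extension with a hysteresis band of 2%
#' of the cycle amplitude (robust to noise, no peak-picking parameters).
#' With `nCycles = 0` in the protocol, everything after the preload is
#' labelled ramp.
#'
#' @param trace a [ForceExtensionTrace-class].
#' @param protocol a [TestProtocol-class].
#' @return the trace with `segmentLabels()` filled in.
#' @export
segmentTrace <- function(trace, protocol) {
  validObject(trace)
  x <- trace@extension
  n <- length(x)
  seg <- rep("ramp", n)
  dx <- diff(x)
  dec <- which(dx < -1e-12)
  rampStart <- if (length(dec)) dec[length(dec)] + 1L else 1L
  if (protocol@nCycles > 0L) {
    if (rampStart < 3L)
      stop("protocol mismatch: no oscillatory preconditioning segment found")
    pre <- x[seq_len(rampStart)]
    base <- x[rampStart]
    amp <- max(pre) - base
    if (amp <= 0)
      stop("protocol mismatch: no oscillatory preconditioning segment found")
    centre <- base + amp / 2
    band <- 0.02 * amp
    state <- pre[1] > centre
    ups <- integer()
    for (i in seq_along(pre)) {
      if (!state && pre[i] > centre + band / 2) { state <- TRUE; ups <- c(ups, i) }
      else if (state && pre[i] < centre - band / 2) state <- FALSE
    }
    if (length(ups) != protocol@nCycles)
      stop(sprintf("protocol mismatch: detected %d cycles, expected %d",
                   length(ups), protocol@nCycles))
    before <- pre[seq_len(ups[1])]
    # cycle baseline: the extension the command returns to between cycles
    tol <- 1e-9 * max(1, amp)
    atBase <- which(before <= base + tol)
    if (!length(atBase))
      stop("protocol mismatch: cycles do not return to a common baseline")
    precondStart <- max(atBase)
    seg[seq_len(max(precondStart - 1L, 0L))] <- "preload"
    seg[precondStart:rampStart] <- "preconditioning"
    if (rampStart < n) seg[(rampStart + 1L):n] <- "ramp"
    else stop("protocol mismatch: no ramp segment after preconditioning")
  } else {
    pe <- preloadEndIndex(trace, protocol)
    if (pe > 1L) seg[seq_len(pe - 1L)] <- "preload"
  }
  new("ForceExtensionTrace", time = trace@time, force = trace@force,
      extension = trace@extension, segment = seg,
      sampleRate = trace@sampleRate)
}

# first sample at which force >= preload is sustained for 0.1 s
preloadEndIndex <- function(trace, protocol) {
  w <- max(1L, as.integer(round(0.1 * trace@sampleRate)))
  ok <- trace@force >= protocol@preload
  n <- length(ok)
  if (n < w) stop("trace shorter than the preload sustain window")
  run <- cumsum(ok) - c(rep(0, w), head(cumsum(ok), n - w))
  idx <- which(run[seq.int(w, n)] == w)
  if (!length(idx)) stop("preload force level never sustained for 0.1 s")
  idx[1]
}

# indices of a labelled segment
segmentIndices <- function(trace, label) {
  if (!length(trace@segment)) stop("trace is unsegmented; run segmentTrace()")
  which(trace@segment == label)
}
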