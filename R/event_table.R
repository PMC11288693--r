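#' Event-level cytometry container
#'
#' An `EventTable` holds one acquired sample: an events x channels intensity
#' matrix on the linear (instrument) scale, the channel names, a role for
#' every channel, and the sample identifier.  Event (row) order is the
#' acquisition order; the time channel, when present, must be non-decreasing.
#'
#' @param intensities Numeric matrix, events in rows, channels in columns.
#' @param channel_names Character vector of channel names; defaults to the
#'   column names of `intensities`.
#' @param channel_roles Named character vector mapping each channel to one of
#'   `"marker"`, `"scatter"`, `"time"`, `"viability"`, `"bead"`.
#' @param sample_id Single string identifying the sample.
#'
#' @return An object of class `EventTable`.
#' @export
event_table <- function(intensities, channel_names = colnames(intensities),
                        channel_roles, sample_id = "sample") {
  if (!is.matrix(intensities) || !is.numeric(intensities)) {
    stop("`intensities` must be a numeric matrix")
  }
  if (is.null(channel_names) || length(channel_names) != ncol(intensities)) {
    stop("`channel_names` must name every column of `intensities`")
  }
  if (anyNA(intensities)) stop("event intensities must not contain missing values")
  roles <- channel_roles[channel_names]
  if (anyNA(roles)) {
    stop("channel role map is incomplete for: ",
         paste(channel_names[is.na(roles)], collapse = ", "))
  }
  ok <- roles %in% c("marker", "scatter", "time", "viability", "bead")
  if (!all(ok)) stop("unknown channel role(s): ", paste(unique(roles[!ok]), collapse = ", "))
  if (!any(roles == "marker")) stop("an EventTable needs at least one marker channel")
  colnames(intensities) <- channel_names
  tch <- channel_names[roles == "time"]
  if (length(tch) > 1) stop("at most one time channel is allowed")
  if (length(tch) == 1 && is.unsorted(intensities[, tch])) {
    stop("time channel must be non-decreasing in acquisition order")
  }
  structure(
    list(exprs = intensities, channels = channel_names,
         roles = stats::setNames(as.character(roles), channel_names),
         sample_id = as.character(sample_id)),
    class = "EventTable")
}

#' @export
print.EventTable <- function(x, ...) {
  cat(sprintf("EventTable '%s': %d events x %d channels\n",
              x$sample_id, nrow(x$exprs), ncol(x$exprs)))
  tab <- table(x$roles)
  cat("  roles:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Number of events in an EventTable
#' @param x An `EventTable`.
#' @return Integer event count.
#' @export
n_events <- function(x) nrow(x$exprs)

#' Channels of a given role
#' @param x An `EventTable`.
#' @param role Role to select, e.g. `"marker"`.
#' @return Character vector of channel names.
#' @export
channels_by_role <- function(x, role) x$channels[x$roles == role]

#' Subset the events of an EventTable
#' @param x An `EventTable`.
#' @param i Row (event) index, logical or integer.
#' @return An `EventTable` with the selected events, order preserved.
#' @export
subset_events <- function(x, i) {
  x$exprs <- x$exprs[i, , drop = FALSE]
  x
}

# ---- CSV events dialect ------------------------------------------------
# Comma-separated, header row of channel names, UTF-8, '.' decimal.  Roles
# travel in a sidecar map supplied by the caller (the run configuration).

#' Read event-level data
#'
#' Reads one sample from disk, either from the FCS 3.0 subset written by
#' [write_events()] (float data type; `$PnN`/`$PnS`/`$TOT`/`$PAR` TEXT
#' keywords) or from the CSV events dialect (header row of channel names,
#' one row per event).  For CSV input the channel role map must be supplied
#' by the caller; for FCS it is recovered from the `$PnS` keywords.
#'
#' @param path File to read.
#' @param dialect `"fcs"` or `"csv"`.
#' @param channel_roles Named character role map (required for CSV).
#' @param sample_id Sample identifier; defaults to the file name.
#' @return An [event_table()].
#' @export
read_events <- function(path, dialect = c("fcs", "csv"), channel_roles = NULL,
                        sample_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(sample_id)) sample_id <- sub("\\.[^.]*$", "", basename(path))
  if (dialect == "csv") {
    if (is.null(channel_roles)) {
      stop("reading CSV events requires a `channel_roles` sidecar map")
    }
    dt <- data.table::fread(path, sep = ",", header = TRUE, data.table = FALSE)
    m <- as.matrix(dt)
    storage.mode(m) <- "double"
    return(event_table(m, colnames(m), channel_roles, sample_id))
  }
  read_fcs(path, channel_roles = channel_roles, sample_id = sample_id)
}

#' Write event-level data
#'
#' @param x An `EventTable`.
#' @param path Output file.
#' @param dialect `"fcs"` (FCS 3.0, 32-bit float) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_events <- function(x, path, dialect = c("fcs", "csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") {
    data.table::fwrite(data.table::as.data.table(x$exprs), path, sep = ",")
  } else {
    write_fcs(x, path)
  }
  invisible(path)
}

# ---- FCS 3.0 subset ----------------------------------------------------
# Minimal FCS 3.0: 58-byte HEADER with segment offsets, a primary TEXT
# segment, and a little-endian 32-bit float DATA segment in list mode.
# Only the keywords this pipeline needs are written; the reader insists on
# $TOT, $PAR, $DATATYPE F and per-parameter $PnN.

write_fcs <- function(x, path) {
  m <- x$exprs
  npar <- ncol(m); ntot <- nrow(m)
  kw <- c(
    "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
    "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
    "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
    "$NEXTDATA" = "0",
    "$PAR" = as.character(npar), "$TOT" = as.character(ntot),
    "$FIL" = basename(path), "$SRC" = x$sample_id)
  for (i in seq_len(npar)) {
    kw[sprintf("$P%dB", i)] <- "32"
    kw[sprintf("$P%dE", i)] <- "0,0"
    kw[sprintf("$P%dR", i)] <- "262144"
    kw[sprintf("$P%dN", i)] <- x$channels[i]
    kw[sprintf("$P%dS", i)] <- x$roles[x$channels[i]]
  }
  # data offsets depend on TEXT length; write them fixed-width so the
  # length of TEXT does not change once they are filled in
  kw <- c("$BEGINDATA" = strrep(" ", 10), "$ENDDATA" = strrep(" ", 10), kw)
  render <- function(kv) {
    paste0("/", paste(rbind(names(kv), unname(kv)), collapse = "/"), "/")
  }
  text_start <- 58L
  text_len <- nchar(render(kw), type = "bytes")
  data_start <- text_start + text_len
  data_len <- 4L * npar * ntot
  kw["$BEGINDATA"] <- formatC(data_start, width = 10)
  kw["$ENDDATA"] <- formatC(data_start + data_len - 1L, width = 10)
  txt <- render(kw)
  stopifnot(nchar(txt, type = "bytes") == text_len)
  header <- sprintf("FCS3.0    %8d%8d%8d%8d%8d%8d",
                    text_start, text_start + text_len - 1L,
                    data_start, data_start + data_len - 1L, 0L, 0L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(txt, con, eos = NULL)
  writeBin(as.vector(t(m)), con, size = 4, endian = "little")
  invisible(path)
}

read_fcs <- function(path, channel_roles = NULL, sample_id = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readChar(con, 58L, useBytes = TRUE)
  if (substr(header, 1, 6) != "FCS3.0") stop("not an FCS 3.0 file: ", path)
  off <- suppressWarnings(as.integer(substring(header,
                                               c(11, 19, 27, 35), c(18, 26, 34, 42))))
  if (anyNA(off)) stop("malformed FCS header: unreadable segment offsets")
  seek(con, off[1])
  txt <- readChar(con, off[2] - off[1] + 1L, useBytes = TRUE)
  delim <- substr(txt, 1, 1)
  parts <- strsplit(substring(txt, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  kw <- stats::setNames(trimws(parts[seq(2, length(parts), 2)]),
                        parts[seq(1, length(parts), 2)])
  need <- function(k) {
    if (is.na(kw[k]) || !nzchar(kw[k])) stop("FCS parse error: missing keyword ", k)
    kw[[k]]
  }
  npar <- as.integer(need("$PAR"))
  ntot <- as.integer(need("$TOT"))
  if (need("$DATATYPE") != "F") stop("FCS parse error: only $DATATYPE F is supported")
  chans <- vapply(seq_len(npar), function(i) need(sprintf("$P%dN", i)), "")
  roles_kw <- vapply(seq_len(npar), function(i) {
    v <- kw[sprintf("$P%dS", i)]
    if (is.na(v)) "" else v
  }, "")
  seek(con, off[3])
  vals <- readBin(con, "numeric", n = npar * ntot, size = 4, endian = "little")
  m <- matrix(vals, nrow = ntot, ncol = npar, byrow = TRUE,
              dimnames = list(NULL, chans))
  roles <- channel_roles
  if (is.null(roles)) {
    if (!all(nzchar(roles_kw))) {
      stop("channel role map incomplete: no $PnS roles in file and none supplied")
    }
    roles <- stats::setNames(roles_kw, chans)
  }
  event_table(m, chans, roles,
              if (is.null(sample_id)) need("$SRC") else sample_id)
}

# ---- compensation ------------------------------------------------------

#' Spillover matrix
#'
#' Square matrix indexed by marker channels; row = source dye, column =
#' detected channel, diagonal fixed at 1.  Observed intensities relate to
#' true ones by `observed = true %*% S`.
#'
#' @param m Square numeric matrix with identical row and column names.
#' @return A validated spillover matrix (class `SpilloverMatrix`).
#' @export
spillover_matrix <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("spillover matrix must be square")
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m))) {
    stop("spillover matrix needs identical row and column channel names")
  }
  if (any(abs(diag(m) - 1) > 1e-12)) stop("spillover matrix diagonal must be 1")
  k <- kappa(m, exact = TRUE)
  if (!is.finite(k) || k > 1e10) {
    stop(sprintf("spillover matrix is numerically singular (condition number %.3g)", k))
  }
  structure(m, class = c("SpilloverMatrix", "matrix", "array"))
}

#' Compensate marker channels for spillover
#'
#' Solves `X' %*% S = X` on the marker channels named by `S`; all other
#' channels are left untouched.
#'
#' @param events An `EventTable` (linear scale).
#' @param S A [spillover_matrix()].
#' @return The compensated `EventTable`.
#' @export
compensate <- function(events, S) {
  ch <- rownames(S)
  miss <- setdiff(ch, channels_by_role(events, "marker"))
  if (length(miss)) stop("spillover channels absent from marker channels: ",
                         paste(miss, collapse = ", "))
  events$exprs[, ch] <- events$exprs[, ch, drop = FALSE] %*% solve(unclass(S))
  events
}
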