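# Minimal DICOM codec: explicit VR little endian only, covering the tag
# subset the toolkit exchanges (CT slices, RTSTRUCT, RTDOSE, private
# shift/roll tags).  Files carry the standard 128-byte preamble, "DICM"
# marker and a file meta group declaring transfer syntax 1.2.840.10008.1.2.1.
#
# An element is list(group, element, vr, value); SQ values are lists of
# items, each item a list of elements.  String multi-values are encoded
# with the usual backslash separator.

TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

dcm_el <- function(group, element, vr, value) {
  list(group = group, element = element, vr = vr, value = value)
}

dcm_uid <- function() {
  paste0("1.2.826.0.1.3680043.9999.",
         paste(sample.int(9999L, 3L, replace = TRUE), collapse = "."),
         ".", as.integer(Sys.time()) %% 100000L)
}

.u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
.u32 <- function(x) {
  x <- as.numeric(x)
  lo <- x %% 65536; hi <- (x - lo) / 65536
  c(writeBin(as.integer(lo), raw(), size = 2, endian = "little"),
    writeBin(as.integer(hi), raw(), size = 2, endian = "little"))
}

.str_bytes <- function(s, pad) {
  b <- charToRaw(as.character(s))
  if (length(b) %% 2 == 1) b <- c(b, pad)
  b
}

.int16_bytes <- function(v) {
  v <- as.integer(round(v))
  v[v > 32767L] <- v[v > 32767L] - 65536L   # encode unsigned range
  writeBin(v, raw(), size = 2, endian = "little")
}

.long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

.value_bytes <- function(vr, value) {
  if (vr == "DS" && is.numeric(value)) value <- sprintf("%.10g", value)
  if (vr == "IS" && is.numeric(value)) value <- as.character(as.integer(value))
  switch(vr,
    UI = .str_bytes(paste(value, collapse = "\\"), as.raw(0)),
    SH = , LO = , CS = , DA = , TM = , DS = , IS = , PN = , ST = , LT = ,
    AE = .str_bytes(paste(value, collapse = "\\"), charToRaw(" ")),
    US = writeBin(as.integer(value), raw(), size = 2, endian = "little"),
    UL = .u32(value),
    FL = writeBin(as.numeric(value), raw(), size = 4, endian = "little"),
    FD = writeBin(as.numeric(value), raw(), size = 8, endian = "little"),
    OW = .int16_bytes(value),
    OB = as.raw(value),
    stop("unsupported VR for writing: ", vr))
}

.encode_element <- function(e) {
  if (e$vr == "SQ") {
    items <- lapply(e$value, function(item) {
      body <- do.call(c, c(lapply(item, .encode_element), list(raw(0))))
      c(.u16(0xFFFE), .u16(0xE000), .u32(length(body)), body)
    })
    body <- do.call(c, c(items, list(raw(0))))
    return(c(.u16(e$group), .u16(e$element), charToRaw("SQ"), as.raw(c(0, 0)),
             .u32(length(body)), body))
  }
  body <- .value_bytes(e$vr, e$value)
  hdr <- c(.u16(e$group), .u16(e$element), charToRaw(e$vr))
  if (e$vr %in% .long_vrs) {
    c(hdr, as.raw(c(0, 0)), .u32(length(body)), body)
  } else {
    if (length(body) > 65534) stop("value too long for short-form VR ", e$vr)
    c(hdr, .u16(length(body)), body)
  }
}

# Write a DICOM file: `elements` is the dataset (list of dcm_el), sorted here.
dcm_write <- function(elements, path, sop_class = "1.2.840.10008.5.1.4.1.1.2",
                      sop_instance = NULL) {
  ord <- order(vapply(elements, function(e) e$group * 65536 + e$element,
                      numeric(1)))
  elements <- elements[ord]
  if (is.null(sop_instance)) sop_instance <- dcm_uid()
  meta <- list(
    dcm_el(0x0002, 0x0001, "OB", c(0L, 1L)),
    dcm_el(0x0002, 0x0002, "UI", sop_class),
    dcm_el(0x0002, 0x0003, "UI", sop_instance),
    dcm_el(0x0002, 0x0010, "UI", TS_EXPLICIT_LE),
    dcm_el(0x0002, 0x0012, "UI", "1.2.826.0.1.3680043.9999.1"))
  meta_body <- do.call(c, lapply(meta, .encode_element))
  meta_all <- c(.encode_element(dcm_el(0x0002, 0x0000, "UL",
                                       length(meta_body))), meta_body)
  data_body <- do.call(c, lapply(elements, .encode_element))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta_all, data_body), con)
  invisible(path)
}

.rd_u16 <- function(b, pos) {
  as.integer(b[pos]) + 256L * as.integer(b[pos + 1L])
}
.rd_u32 <- function(b, pos) {
  as.numeric(b[pos]) + 256 * as.numeric(b[pos + 1L]) +
    65536 * as.numeric(b[pos + 2L]) + 16777216 * as.numeric(b[pos + 3L])
}

.parse_value <- function(vr, bytes) {
  n <- length(bytes)
  switch(vr,
    UI = , SH = , LO = , CS = , DA = , TM = , PN = , ST = , LT = , AE = {
      s <- rawToChar(bytes[bytes != as.raw(0)])
      strsplit(trimws(s), "\\", fixed = TRUE)[[1]]
    },
    DS = , IS = {
      s <- rawToChar(bytes[bytes != as.raw(0)])
      as.numeric(strsplit(trimws(s), "\\", fixed = TRUE)[[1]])
    },
    US = readBin(bytes, "integer", n = n / 2, size = 2, signed = FALSE,
                 endian = "little"),
    UL = readBin(bytes, "integer", n = n / 4, size = 4, endian = "little"),
    FL = readBin(bytes, "numeric", n = n / 4, size = 4, endian = "little"),
    FD = readBin(bytes, "numeric", n = n / 8, size = 8, endian = "little"),
    OW = readBin(bytes, "integer", n = n / 2, size = 2, signed = TRUE,
                 endian = "little"),
    bytes)
}

# parse a dataset byte range; returns list(elements, next position)
.parse_dataset <- function(b, pos, end) {
  out <- list()
  while (pos + 7 <= end + 1) {
    group <- .rd_u16(b, pos); elem <- .rd_u16(b, pos + 2L)
    if (group == 0xFFFE) {                       # item / delimiter tags
      len <- .rd_u32(b, pos + 4L)
      if (elem %in% c(0xE00D, 0xE0DD)) return(list(out, pos + 8L, elem))
      stop("unexpected item tag outside sequence")
    }
    vr <- rawToChar(b[(pos + 4L):(pos + 5L)])
    if (vr %in% .long_vrs) {
      len <- .rd_u32(b, pos + 8L); hdr <- 12L
    } else {
      len <- .rd_u16(b, pos + 6L); hdr <- 8L
    }
    pos <- pos + hdr
    if (vr == "SQ") {
      sq_end <- if (len == 4294967295) end else pos + len - 1L
      items <- list()
      ipos <- pos
      while (ipos + 7 <= sq_end + 1) {
        ig <- .rd_u16(b, ipos); ie <- .rd_u16(b, ipos + 2L)
        ilen <- .rd_u32(b, ipos + 4L)
        if (ig == 0xFFFE && ie == 0xE0DD) { ipos <- ipos + 8L; break }
        if (!(ig == 0xFFFE && ie == 0xE000)) stop("malformed sequence item")
        ipos <- ipos + 8L
        iend <- if (ilen == 4294967295) sq_end else ipos + ilen - 1L
        res <- .parse_dataset(b, ipos, iend)
        items[[length(items) + 1L]] <- res[[1]]
        ipos <- res[[2]]
        if (len != 4294967295 && ipos > sq_end) break
      }
      out[[length(out) + 1L]] <- dcm_el(group, elem, "SQ", items)
      pos <- if (len == 4294967295) ipos else pos + len
    } else {
      val <- .parse_value(vr, b[seq_len(len) + pos - 1L])
      out[[length(out) + 1L]] <- dcm_el(group, elem, vr, val)
      pos <- pos + len
    }
  }
  list(out, pos, NA)
}

# Read a DICOM file written in explicit VR little endian.
dcm_read <- function(path) {
  b <- readBin(path, "raw", n = file.size(path))
  if (length(b) < 140 || rawToChar(b[129:132]) != "DICM")
    stop("not a DICOM file: ", path)
  pos <- 133L
  # file meta group (always explicit LE)
  g <- .rd_u16(b, pos)
  if (g != 2L) stop("missing file meta group: ", path)
  meta_len <- .parse_value("UL", b[(pos + 8L):(pos + 11L)])
  pos <- pos + 12L
  meta <- .parse_dataset(b, pos, pos + meta_len - 1L)
  ts <- dcm_get(meta[[1]], 0x0002, 0x0010)
  if (!is.null(ts) && !identical(ts, TS_EXPLICIT_LE))
    stop("unsupported transfer syntax: ", ts)
  .parse_dataset(b, pos + meta_len, length(b))[[1]]
}

# First matching top-level element value, or NULL.
dcm_get <- function(elements, group, element) {
  for (e in elements)
    if (e$group == group && e$element == element) return(e$value)
  NULL
}
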