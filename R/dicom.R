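# Minimal DICOM codec: Explicit VR Little Endian, the tag subset needed for
# CT/MR geometry slices and RT Structure Sets. Values are kept as raw vectors
# so that untouched elements re-serialize byte-identically.

UID_TRANSFER_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
UID_SOP_CT <- "1.2.840.10008.5.1.4.1.1.2"
UID_SOP_MR <- "1.2.840.10008.5.1.4.1.1.4"
UID_SOP_RTSTRUCT <- "1.2.840.10008.5.1.4.1.1.481.3"
UID_IMPLEMENTATION <- "2.25.83451735129843571"

# VRs whose length field is 4 bytes after 2 reserved bytes
.long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

u16le <- function(x) {
  x <- as.integer(x)
  as.raw(c(x %% 256L, (x %/% 256L) %% 256L))
}

u32le <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256, (x %/% 16777216) %% 256))
}

rd_u16 <- function(bytes, i) {
  as.integer(bytes[i]) + 256L * as.integer(bytes[i + 1L])
}

rd_u32 <- function(bytes, i) {
  as.numeric(bytes[i]) + 256 * as.numeric(bytes[i + 1L]) +
    65536 * as.numeric(bytes[i + 2L]) + 16777216 * as.numeric(bytes[i + 3L])
}

#' Construct a DICOM data element
#'
#' @param group,element Integer tag parts.
#' @param vr Two-letter value representation.
#' @param value Raw vector (stored verbatim), character vector (joined with
#'   `\\` and padded to even length), integers for `US`/`UL`, or for `SQ` a
#'   list of items where each item is a list of elements.
#' @return A `dcm_element` list.
#' @keywords internal
dcm_element <- function(group, element, vr, value) {
  if (vr == "SQ") {
    stopifnot(is.list(value))
  } else if (is.raw(value)) {
    # verbatim
  } else if (vr %in% c("US")) {
    value <- do.call(c, lapply(as.integer(value), u16le))
  } else if (vr %in% c("UL")) {
    value <- do.call(c, lapply(as.numeric(value), u32le))
  } else {
    s <- paste(as.character(value), collapse = "\\")
    value <- charToRaw(s)
    if (length(value) %% 2L == 1L) {
      pad <- if (vr %in% c("UI", "OB")) as.raw(0L) else charToRaw(" ")
      value <- c(value, pad)
    }
  }
  list(group = as.integer(group), element = as.integer(element), vr = vr, value = value)
}

serialize_element <- function(el) {
  header <- c(u16le(el$group), u16le(el$element), charToRaw(el$vr))
  if (el$vr == "SQ") {
    body <- serialize_items(el$value)
    c(header, as.raw(c(0L, 0L)), u32le(length(body)), body)
  } else if (el$vr %in% .long_vrs) {
    c(header, as.raw(c(0L, 0L)), u32le(length(el$value)), el$value)
  } else {
    if (length(el$value) > 65534) {
      stop("value too long for short-VR element", call. = FALSE)
    }
    c(header, u16le(length(el$value)), el$value)
  }
}

serialize_items <- function(items) {
  parts <- lapply(items, function(item) {
    body <- serialize_dataset(item)
    c(u16le(0xFFFEL), u16le(0xE000L), u32le(length(body)), body)
  })
  do.call(c, c(list(raw(0)), parts))
}

serialize_dataset <- function(elements) {
  if (length(elements) == 0) return(raw(0))
  keys <- vapply(elements, function(e) e$group * 65536 + e$element, numeric(1))
  elements <- elements[order(keys)]
  do.call(c, lapply(elements, serialize_element))
}

#' Write a DICOM Part-10 file (Explicit VR Little Endian)
#'
#' @param path Output file.
#' @param sop_class_uid,sop_instance_uid UIDs for the file meta group.
#' @param dataset List of `dcm_element`s.
#' @return `path`, invisibly.
#' @keywords internal
dcm_write_file <- function(path, sop_class_uid, sop_instance_uid, dataset) {
  meta <- list(
    dcm_element(0x0002L, 0x0001L, "OB", as.raw(c(0L, 1L))),
    dcm_element(0x0002L, 0x0002L, "UI", sop_class_uid),
    dcm_element(0x0002L, 0x0003L, "UI", sop_instance_uid),
    dcm_element(0x0002L, 0x0010L, "UI", UID_TRANSFER_EXPLICIT_LE),
    dcm_element(0x0002L, 0x0012L, "UI", UID_IMPLEMENTATION)
  )
  meta_bytes <- serialize_dataset(meta)
  group_len <- serialize_element(dcm_element(0x0002L, 0x0000L, "UL", length(meta_bytes)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(group_len, meta_bytes, serialize_dataset(dataset)), con)
  invisible(path)
}

parse_elements <- function(bytes, pos, end) {
  elements <- list()
  n <- 0L
  while (pos < end) {
    group <- rd_u16(bytes, pos)
    element <- rd_u16(bytes, pos + 2L)
    pos <- pos + 4L
    if (group == 0xFFFEL) {
      # sequence/item delimitation inside undefined-length content
      pos <- pos + 4L  # skip length
      if (element == 0xE0DDL || element == 0xE00DL) break
      stop("unexpected item tag outside sequence", call. = FALSE)
    }
    vr <- rawToChar(bytes[pos:(pos + 1L)])
    pos <- pos + 2L
    if (vr %in% .long_vrs) {
      len <- rd_u32(bytes, pos + 2L)
      pos <- pos + 6L
    } else {
      len <- rd_u16(bytes, pos)
      pos <- pos + 2L
    }
    if (vr == "SQ") {
      if (len == 4294967295) {
        parsed <- parse_items(bytes, pos, length(bytes) + 1L, undefined = TRUE)
      } else {
        parsed <- parse_items(bytes, pos, pos + len, undefined = FALSE)
      }
      value <- parsed$items
      pos <- parsed$pos
    } else {
      if (len == 4294967295) stop("undefined length on non-SQ element", call. = FALSE)
      value <- if (len > 0) bytes[pos:(pos + len - 1L)] else raw(0)
      pos <- pos + len
    }
    n <- n + 1L
    elements[[n]] <- list(group = group, element = element, vr = vr, value = value)
  }
  list(elements = elements, pos = pos)
}

parse_items <- function(bytes, pos, end, undefined) {
  items <- list()
  n <- 0L
  while (pos < end) {
    group <- rd_u16(bytes, pos)
    element <- rd_u16(bytes, pos + 2L)
    len <- rd_u32(bytes, pos + 4L)
    pos <- pos + 8L
    if (group == 0xFFFEL && element == 0xE0DDL) break  # sequence delimiter
    if (!(group == 0xFFFEL && element == 0xE000L)) {
      stop("malformed sequence item", call. = FALSE)
    }
    if (len == 4294967295) {
      parsed <- parse_elements(bytes, pos, end)
    } else {
      parsed <- parse_elements(bytes, pos, pos + len)
    }
    n <- n + 1L
    items[[n]] <- parsed$elements
    pos <- parsed$pos
  }
  list(items = items, pos = pos)
}

#' Read a DICOM Part-10 file
#'
#' Only the Explicit VR Little Endian transfer syntax is supported; other
#' syntaxes raise an error.
#'
#' @param path File path.
#' @return List with `meta` and `dataset`, each a list of `dcm_element`s.
#' @keywords internal
dcm_read_file <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 140 || rawToChar(bytes[129:132]) != "DICM") {
    stop("not a DICOM Part-10 file: ", path, call. = FALSE)
  }
  pos <- 133L
  # file meta group is always Explicit VR LE; read elements while group == 0002
  meta <- list()
  repeat {
    group <- rd_u16(bytes, pos)
    if (group != 0x0002L) break
    parsed <- parse_one_meta(bytes, pos)
    meta[[length(meta) + 1L]] <- parsed$el
    pos <- parsed$pos
  }
  ts <- dcm_string(dcm_find(meta, 0x0002L, 0x0010L))
  if (!identical(ts, UID_TRANSFER_EXPLICIT_LE)) {
    stop("unsupported transfer syntax: ", ts, call. = FALSE)
  }
  dataset <- parse_elements(bytes, pos, length(bytes) + 1L)$elements
  list(meta = meta, dataset = dataset)
}

parse_one_meta <- function(bytes, pos) {
  group <- rd_u16(bytes, pos)
  element <- rd_u16(bytes, pos + 2L)
  vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
  pos <- pos + 6L
  if (vr %in% .long_vrs) {
    len <- rd_u32(bytes, pos + 2L)
    pos <- pos + 6L
  } else {
    len <- rd_u16(bytes, pos)
    pos <- pos + 2L
  }
  value <- if (len > 0) bytes[pos:(pos + len - 1L)] else raw(0)
  list(el = list(group = group, element = element, vr = vr, value = value),
       pos = pos + len)
}

# ---- element lookup / decoding -------------------------------------------

dcm_find <- function(elements, group, element) {
  for (el in elements) {
    if (el$group == group && el$element == element) return(el)
  }
  NULL
}

dcm_string <- function(el) {
  if (is.null(el) || length(el$value) == 0) return(NULL)
  s <- rawToChar(el$value[el$value != as.raw(0)])
  sub(" +$", "", s)
}

dcm_strings <- function(el) {
  s <- dcm_string(el)
  if (is.null(s)) return(character(0))
  strsplit(s, "\\", fixed = TRUE)[[1]]
}

dcm_numeric <- function(el) {
  as.numeric(dcm_strings(el))
}

dcm_u16 <- function(el) {
  if (is.null(el)) return(NULL)
  rd_u16(el$value, 1L)
}

# replace (or append) an element in a flat element list, keeping tag order
dcm_set <- function(elements, group, element, vr, value) {
  el <- dcm_element(group, element, vr, value)
  for (i in seq_along(elements)) {
    if (elements[[i]]$group == group && elements[[i]]$element == element) {
      elements[[i]] <- el
      return(elements)
    }
  }
  c(elements, list(el))
}

ds_fmt <- function(x) {
  # DS values are limited to 16 bytes; 6 significant digits are ample for mm
  sub("\\.?0+$", "", sprintf("%.4f", x))
}

new_sop_instance_uid <- function(uid) {
  if (is.null(uid) || !nzchar(uid)) return("2.25.1")
  if (nchar(uid) <= 62) paste0(uid, ".1") else paste0(substr(uid, 1, 62), ".1")
}
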