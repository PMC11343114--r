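# OME-TIFF input/output for multichannel stacks.
#
# Reading goes through tiff::readTIFF, which handles float32 pages and
# exposes the ImageDescription tag. Writing is done by a small built-in
# OME-TIFF writer (uncompressed float32, one strip per plane, sorted tags,
# OME-XML description embedding voxel sizes, channel names and metadata):
# this keeps voxel sizes inside the file, which is required for every
# downstream micrometer quantity.

OME_NS <- "http://www.openmicroscopy.org/Schemas/OME/2016-06"

ome_xml <- function(stack) {
  g <- stack$grid
  ch <- names(stack$channels)
  md <- stack$metadata
  esc <- function(x) xml2::xml_text(xml2::read_xml(
    paste0("<x>", gsub("&", "&amp;", gsub("<", "&lt;", as.character(x))), "</x>")))
  channels <- paste(sprintf('<Channel ID="Channel:0:%d" Name="%s" SamplesPerPixel="1"/>',
                            seq_along(ch) - 1L, vapply(ch, esc, "")),
                    collapse = "")
  meta_attrs <- paste(vapply(c("animal", "group", "region", "age"), function(k) {
    v <- md[[k]]
    if (is.null(v)) "" else sprintf(' %s="%s"', k, esc(v))
  }, ""), collapse = "")
  sprintf(paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<OME xmlns="%s">',
    '<Image ID="Image:0"><Pixels ID="Pixels:0" DimensionOrder="XYCZT" ',
    'Type="float" SizeX="%d" SizeY="%d" SizeZ="%d" SizeC="%d" SizeT="1" ',
    'PhysicalSizeX="%.17g" PhysicalSizeY="%.17g" PhysicalSizeZ="%.17g" ',
    'PhysicalSizeXUnit="µm" PhysicalSizeYUnit="µm" ',
    'PhysicalSizeZUnit="µm">%s<TiffData/></Pixels></Image>',
    '<StructuredAnnotations><XMLAnnotation ID="Annotation:0"><Value>',
    '<gliamorph%s/>',
    '</Value></XMLAnnotation></StructuredAnnotations></OME>'),
    OME_NS, g$shape[3], g$shape[2], g$shape[1], length(ch),
    g$voxel_size[3], g$voxel_size[2], g$voxel_size[1], channels, meta_attrs)
}

# one 12-byte IFD entry
tiff_entry <- function(con, tag, type, count, value, value_is_offset = FALSE) {
  writeBin(as.integer(tag), con, size = 2, endian = "little")
  writeBin(as.integer(type), con, size = 2, endian = "little")
  writeBin(as.integer(count), con, size = 4, endian = "little")
  if (type == 3 && !value_is_offset) {  # SHORT packed into 4 bytes
    writeBin(as.integer(value), con, size = 2, endian = "little")
    writeBin(0L, con, size = 2, endian = "little")
  } else {
    writeBin(as.integer(value), con, size = 4, endian = "little")
  }
}

#' Write a multichannel stack as OME-TIFF
#'
#' Writes an uncompressed 32-bit float OME-TIFF with plane order XYCZT
#' (channel fastest), voxel sizes, channel names and animal metadata
#' embedded in the OME-XML ImageDescription. [read_stack()] of the written
#' file reproduces the stack bit-identically.
#'
#' @param stack a [multichannel_stack].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "multichannel_stack"))
  g <- stack$grid
  nz <- g$shape[1]; ny <- g$shape[2]; nx <- g$shape[3]
  nc <- length(stack$channels)
  if (nc == 0) stop("stack has no channels")

  desc <- charToRaw(enc2utf8(ome_xml(stack)))
  desc <- c(desc, as.raw(0L))                      # NUL-terminated ASCII tag
  desc_len <- length(desc)
  if (desc_len %% 2 == 1) desc <- c(desc, as.raw(0L))
  strip_bytes <- ny * nx * 4L
  npages <- nz * nc
  desc_off <- 8L
  strip_off <- function(p) desc_off + length(desc) + (p - 1L) * strip_bytes
  ifd0_off <- desc_off + length(desc) + npages * strip_bytes
  ifd_size <- function(p) 2L + 12L * (if (p == 1L) 11L else 10L) + 4L
  ifd_off <- desc_off + length(desc) + npages * strip_bytes +
    c(0L, cumsum(vapply(seq_len(npages - 1L), ifd_size, 1L)))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(ifd0_off, con, size = 4, endian = "little")
  writeBin(desc, con)
  # pixel data: plane order z outer, c inner (XYCZT), rows = y, cols = x
  for (z in seq_len(nz))
    for (c in seq_len(nc)) {
      plane <- stack$channels[[c]][z, , ]
      writeBin(writeBin(as.numeric(t(plane)), raw(), size = 4L,
                        endian = "little"), con)
    }
  for (p in seq_len(npages)) {
    ntags <- if (p == 1L) 11L else 10L
    writeBin(ntags, con, size = 2, endian = "little")
    tiff_entry(con, 256, 4, 1, nx)                    # ImageWidth
    tiff_entry(con, 257, 4, 1, ny)                    # ImageLength
    tiff_entry(con, 258, 3, 1, 32)                    # BitsPerSample
    tiff_entry(con, 259, 3, 1, 1)                     # Compression: none
    tiff_entry(con, 262, 3, 1, 1)                     # Photometric: min-is-black
    if (p == 1L)
      tiff_entry(con, 270, 2, desc_len, desc_off, TRUE)  # ImageDescription
    tiff_entry(con, 273, 4, 1, strip_off(p))          # StripOffsets
    tiff_entry(con, 277, 3, 1, 1)                     # SamplesPerPixel
    tiff_entry(con, 278, 4, 1, ny)                    # RowsPerStrip
    tiff_entry(con, 279, 4, 1, strip_bytes)           # StripByteCounts
    tiff_entry(con, 339, 3, 1, 3)                     # SampleFormat: IEEE float
    nxt <- if (p < npages) ifd_off[p + 1L] else 0L
    writeBin(as.integer(nxt), con, size = 4, endian = "little")
  }
  invisible(path)
}

parse_ome_description <- function(desc) {
  out <- list()
  doc <- tryCatch(xml2::read_xml(desc), error = function(e) NULL)
  if (is.null(doc)) return(out)
  px <- xml2::xml_find_first(doc, ".//*[local-name()='Pixels']")
  if (inherits(px, "xml_missing")) return(out)
  num <- function(a) suppressWarnings(as.numeric(xml2::xml_attr(px, a)))
  out$size <- c(z = num("SizeZ"), c = num("SizeC"), y = num("SizeY"),
                x = num("SizeX"))
  vs <- c(num("PhysicalSizeZ"), num("PhysicalSizeY"), num("PhysicalSizeX"))
  if (all(is.finite(vs))) out$voxel_size <- vs
  chn <- xml2::xml_find_all(doc, ".//*[local-name()='Channel']")
  if (length(chn)) out$channel_names <- xml2::xml_attr(chn, "Name")
  gm <- xml2::xml_find_first(doc, ".//*[local-name()='gliamorph']")
  if (!inherits(gm, "xml_missing")) {
    md <- list()
    for (k in c("animal", "group", "region", "age")) {
      v <- xml2::xml_attr(gm, k)
      if (!is.na(v)) md[[k]] <- v
    }
    out$metadata <- md
  }
  out
}

#' Read a multichannel stack from TIFF / OME-TIFF
#'
#' Reads a 3D/4D TIFF. Voxel sizes and channel names are taken from the
#' OME-XML ImageDescription when present; otherwise they must be supplied.
#' A file without voxel-size metadata and without a `voxel_size` override is
#' an error, never a silent default: every downstream measurement is in
#' micrometers.
#'
#' @param path TIFF file path.
#' @param channel_map named integer vector mapping channel name to 0-based
#'   channel index within each z-plane group (e.g. `c(iba1 = 0, agrp = 1)`).
#'   Defaults to the channel names stored in the file.
#' @param voxel_size optional (dz, dy, dx) in micrometers, overriding (or
#'   supplying missing) file metadata.
#' @param n_channels number of channels, needed only for plain TIFFs with no
#'   OME metadata (pages are assumed interleaved, channel fastest).
#' @return A [multichannel_stack].
#' @export
read_stack <- function(path, channel_map = NULL, voxel_size = NULL,
                       n_channels = NULL) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  desc <- attr(pages[[1]], "description")
  meta <- if (!is.null(desc)) parse_ome_description(desc) else list()

  if (is.null(voxel_size)) voxel_size <- meta$voxel_size
  if (is.null(voxel_size))
    stop("no voxel-size metadata in file and no voxel_size override given")
  if (any(voxel_size <= 0)) stop("non-positive voxel size")

  nc <- if (!is.null(meta$size) && is.finite(meta$size[["c"]]))
    as.integer(meta$size[["c"]]) else n_channels
  if (is.null(nc)) nc <- 1L
  npages <- length(pages)
  if (npages %% nc != 0) stop("page count not divisible by channel count")
  nz <- npages %/% nc
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])

  if (is.null(channel_map)) {
    nms <- meta$channel_names
    if (is.null(nms)) nms <- paste0("ch", seq_len(nc) - 1L)
    channel_map <- setNames(seq_len(nc) - 1L, nms)
  }
  if (any(channel_map < 0) || any(channel_map >= nc))
    stop("channel index out of range")

  channels <- lapply(channel_map, function(ci) {
    a <- array(0, dim = c(nz, ny, nx))
    for (z in seq_len(nz)) {
      pl <- pages[[(z - 1L) * nc + ci + 1L]]
      a[z, , ] <- pl[, , drop = TRUE]
    }
    a
  })
  md <- meta$metadata
  if (is.null(md)) md <- list()
  multichannel_stack(channels, voxel_grid(c(nz, ny, nx), voxel_size), md)
}

#' Read or write a per-animal metric table
#'
#' Long-format CSV with one row per (animal, region, metric): columns
#' `animal, group, age, region, metric, value`, UTF-8, header row, stable
#' column order. An optional leading `# key: value` comment line (e.g. the
#' pipeline's config hash) is preserved on write and skipped on read.
#'
#' @param x data frame to write.
#' @param path CSV path.
#' @param comment optional single comment line (without the leading `"# "`).
#' @return `read_animal_table` returns the data frame; `write_animal_table`
#'   returns `path` invisibly.
#' @export
write_animal_table <- function(x, path, comment = NULL) {
  con <- file(path, "wb")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  # fixed float formatting keeps regeneration byte-identical
  for (cl in names(x))
    if (is.numeric(x[[cl]])) x[[cl]] <- sprintf("%.10g", x[[cl]])
  write.csv(x, con, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_animal_table
#' @export
read_animal_table <- function(path) {
  first <- readLines(path, n = 1L)
  skip <- if (startsWith(first, "#")) 1L else 0L
  df <- read.csv(path, skip = skip, stringsAsFactors = FALSE)
  for (cl in names(df)) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    if (!anyNA(v) || all(is.na(v) == is.na(df[[cl]]))) {
      if (cl %in% c("value", "d", "x", "y", "z", "response", "intensity"))
        df[[cl]] <- v
    }
  }
  df
}
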