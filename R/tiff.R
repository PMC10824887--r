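# Minimal baseline TIFF codec (internal).
#
# No TIFF-capable package is available in the target environment, so the
# package carries its own reader/writer for the subset of TIFF 6.0 it needs:
# uncompressed, single-sample grayscale, 8- or 16-bit unsigned, multi-page,
# strip-based, either byte order on read (always little-endian on write).
# Voxel spacing and channel/z layout travel in an OME-style ImageDescription
# on the first page.

TIFF_TAGS <- c(ImageWidth = 256L, ImageLength = 257L, BitsPerSample = 258L,
               Compression = 259L, Photometric = 262L, ImageDescription = 270L,
               StripOffsets = 273L, RowsPerStrip = 278L,
               StripByteCounts = 279L, SampleFormat = 339L,
               SamplesPerPixel = 277L)

# planes: list of integer matrices (ny x nx), identical shapes.
tiff_write <- function(path, planes, bits = 16L, description = NULL) {
  stopifnot(bits %in% c(8L, 16L), length(planes) >= 1L)
  ny <- nrow(planes[[1]]); nx <- ncol(planes[[1]])
  maxval <- 2^bits - 1
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)

  w_u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w_u32 <- function(x) {
    # writeBin has no unsigned 32-bit; offsets here stay far below 2^31
    writeBin(as.integer(x), con, size = 4, endian = "little")
  }

  writeBin(charToRaw("II"), con)
  w_u16(42L)
  # layout: [header 8][pixel data][description][IFDs]
  bytes_per_px <- bits / 8L
  plane_bytes <- ny * nx * bytes_per_px
  data_start <- 8L
  desc_raw <- NULL
  desc_offset <- 0L
  ifd0_offset <- data_start + length(planes) * plane_bytes
  if (!is.null(description)) {
    desc_raw <- c(charToRaw(description), as.raw(0L))
    if (length(desc_raw) %% 2L == 1L) desc_raw <- c(desc_raw, as.raw(0L))
    desc_offset <- ifd0_offset
    ifd0_offset <- ifd0_offset + length(desc_raw)
  }
  w_u32(ifd0_offset)

  for (pl in planes) {
    v <- as.integer(round(pmin(pmax(t(pl), 0), maxval)))
    if (bits == 8L) {
      writeBin(as.raw(v), con)
    } else {
      writeBin(v, con, size = 2, endian = "little")
    }
  }
  if (!is.null(desc_raw)) writeBin(desc_raw, con)

  n_pages <- length(planes)
  entry <- function(tag, type, count, value) {
    w_u16(tag); w_u16(type); w_u32(count)
    if (type == 3L && count == 1L) { w_u16(value); w_u16(0L) } else w_u32(value)
  }
  for (p in seq_len(n_pages)) {
    n_entries <- 9L + (if (p == 1L && !is.null(desc_raw)) 1L else 0L)
    w_u16(n_entries)
    entry(TIFF_TAGS[["ImageWidth"]], 3L, 1L, nx)
    entry(TIFF_TAGS[["ImageLength"]], 3L, 1L, ny)
    entry(TIFF_TAGS[["BitsPerSample"]], 3L, 1L, bits)
    entry(TIFF_TAGS[["Compression"]], 3L, 1L, 1L)
    entry(TIFF_TAGS[["Photometric"]], 3L, 1L, 1L)
    if (p == 1L && !is.null(desc_raw))
      entry(TIFF_TAGS[["ImageDescription"]], 2L, length(desc_raw), desc_offset)
    entry(TIFF_TAGS[["StripOffsets"]], 4L, 1L,
          data_start + (p - 1L) * plane_bytes)
    entry(TIFF_TAGS[["SamplesPerPixel"]], 3L, 1L, 1L)
    entry(TIFF_TAGS[["RowsPerStrip"]], 3L, 1L, ny)
    entry(TIFF_TAGS[["StripByteCounts"]], 4L, 1L, plane_bytes)
    # next IFD offset (0 terminates); each IFD is 2 + n*12 + 4 bytes
    if (p < n_pages) {
      here <- ifd0_offset +
        sum(vapply(seq_len(p), function(q) {
          2L + 12L * (9L + (if (q == 1L && !is.null(desc_raw)) 1L else 0L)) + 4L
        }, integer(1)))
      w_u32(here)
    } else {
      w_u32(0L)
    }
  }
  invisible(path)
}

tiff_read <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw_all <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw_all) < 8L) stopf("not a TIFF file: %s", path)
  order_tag <- rawToChar(raw_all[1:2])
  endian <- if (order_tag == "II") "little" else if (order_tag == "MM") "big" else
    stopf("not a TIFF file: %s", path)
  r_int <- function(off, size, n = 1L) {
    # readBin allows signed = FALSE only for sizes 1-2; 4-byte tag values
    # here (offsets, counts) stay far below 2^31 so signed is safe
    readBin(raw_all[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = endian, signed = size > 2L)
  }
  magic <- r_int(2L, 2L)
  if (magic != 42L) stopf("not a baseline TIFF: %s", path)
  ifd_off <- r_int(4L, 4L)

  planes <- list()
  description <- NULL
  while (ifd_off != 0L) {
    n_entries <- r_int(ifd_off, 2L)
    tags <- list()
    for (e in seq_len(n_entries)) {
      eo <- ifd_off + 2L + (e - 1L) * 12L
      tag <- r_int(eo, 2L)
      type <- r_int(eo + 2L, 2L)
      count <- r_int(eo + 4L, 4L)
      size <- c(1L, 1L, 2L, 4L, 8L, 1L, 1L, 2L, 4L, 8L, 4L, 8L)[type]
      total <- size * count
      voff <- if (total <= 4L) eo + 8L else r_int(eo + 8L, 4L)
      val <- switch(as.character(type),
        "1" = r_int(voff, 1L, count),
        "2" = {
          chars <- raw_all[(voff + 1):(voff + count)]
          rawToChar(chars[chars != as.raw(0L)])
        },
        "3" = r_int(voff, 2L, count),
        "4" = r_int(voff, 4L, count),
        NULL)
      tags[[as.character(tag)]] <- val
    }
    g <- function(id, default = NULL) tags[[as.character(TIFF_TAGS[[id]])]] %||% default
    nx <- g("ImageWidth"); ny <- g("ImageLength")
    bits <- g("BitsPerSample", 1L)[1]
    comp <- g("Compression", 1L)
    if (is.null(nx) || is.null(ny)) stopf("malformed TIFF IFD in %s", path)
    if (comp != 1L) stopf("only uncompressed TIFF supported (compression=%d)", comp)
    if (!bits %in% c(8L, 16L)) stopf("only 8/16-bit TIFF supported (bits=%d)", bits)
    spp <- g("SamplesPerPixel", 1L)
    if (spp != 1L) stopf("only single-sample (grayscale) TIFF supported")
    if (is.null(description)) description <- g("ImageDescription")

    offs <- g("StripOffsets"); counts <- g("StripByteCounts")
    if (is.null(offs)) stopf("malformed TIFF (no strip offsets) in %s", path)
    if (is.null(counts)) counts <- rep(ny * nx * bits / 8L, length(offs))
    px <- integer(0)
    for (s in seq_along(offs)) {
      nb <- counts[s]
      seg <- raw_all[(offs[s] + 1):(offs[s] + nb)]
      px <- c(px, if (bits == 8L) as.integer(seg)
              else readBin(seg, "integer", n = nb / 2L, size = 2L,
                           endian = endian, signed = FALSE))
    }
    if (length(px) != nx * ny) stopf("strip data does not match plane size in %s", path)
    m <- matrix(px, nrow = ny, ncol = nx, byrow = TRUE)
    planes[[length(planes) + 1L]] <- m
    ifd_off <- r_int(ifd_off + 2L + n_entries * 12L, 4L)
  }
  list(planes = planes, description = description)
}

# ---- OME-ish description helpers -------------------------------------------

ome_description <- function(nc, nz, ny, nx, spacing, bits = 16L) {
  sprintf(paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<OME xmlns="http://www.openmicroscopy.org/Schemas/OME/2016-06">',
    '<Image ID="Image:0"><Pixels ID="Pixels:0" DimensionOrder="XYCZT" ',
    'Type="uint%d" SizeX="%d" SizeY="%d" SizeC="%d" SizeZ="%d" SizeT="1" ',
    'PhysicalSizeX="%.9g" PhysicalSizeXUnit="µm" ',
    'PhysicalSizeY="%.9g" PhysicalSizeYUnit="µm" ',
    'PhysicalSizeZ="%.9g" PhysicalSizeZUnit="µm"/></Image></OME>'),
    bits, nx, ny, nc, nz, spacing$dx, spacing$dy, spacing$dz)
}

# attribute extraction by regex: the embedded XML is machine-written and flat,
# and this also tolerates OME variants from other writers (e.g. tifffile)
ome_attr <- function(description, name) {
  m <- regmatches(description,
                  regexpr(sprintf('%s="([^"]*)"', name), description))
  if (length(m) == 0) return(NA_character_)
  sub(sprintf('%s="([^"]*)"', name), "\\1", m)
}

parse_ome_description <- function(description) {
  if (is.null(description) || !grepl("PhysicalSize", description))
    return(NULL)
  num <- function(nm) suppressWarnings(as.numeric(ome_attr(description, nm)))
  int <- function(nm) suppressWarnings(as.integer(ome_attr(description, nm)))
  list(dx = num("PhysicalSizeX"), dy = num("PhysicalSizeY"),
       dz = num("PhysicalSizeZ"),
       size_c = int("SizeC"), size_z = int("SizeZ"),
       dimension_order = ome_attr(description, "DimensionOrder"))
}
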