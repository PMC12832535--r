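# Minimal DICOM support for axial CT series: a reader for explicit- and
# implicit-VR little-endian single-frame files, and a writer used to build
# synthetic series. Only the tags needed to reconstruct geometry and HU are
# interpreted; anything exotic (sequences with undefined length, compressed
# transfer syntaxes, oblique orientations) is rejected with a clear error.

.dcmTagKey <- function(group, elem) sprintf("%04X,%04X", group, elem)

.parseDicomFile <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    .stopf("not a DICOM part-10 file: %s", path)
  u16 <- function(at) readBin(raw[at:(at + 1)], "integer", size = 2,
                              endian = "little", signed = FALSE)
  u32 <- function(at) readBin(raw[at:(at + 3)], "integer", size = 4,
                              endian = "little")
  pos <- 133L
  explicit <- TRUE
  metaEnd <- NA_integer_
  elems <- list()
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  repeat {
    if (pos + 7L > length(raw)) break
    group <- u16(pos); elem <- u16(pos + 2L)
    inMeta <- group == 0x0002
    ex <- if (inMeta) TRUE else explicit
    if (ex) {
      vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
      if (vr %in% long_vrs) {
        len <- u32(pos + 8L); hdr <- 12L
      } else {
        len <- u16(pos + 6L); hdr <- 8L
      }
    } else {
      vr <- NA_character_
      len <- u32(pos + 4L); hdr <- 8L
    }
    if (!is.na(len) && len < 0)
      .stopf("undefined-length element (%s) unsupported in %s",
             .dcmTagKey(group, elem), path)
    val <- if (len > 0) raw[(pos + hdr):(pos + hdr + len - 1L)] else raw(0)
    elems[[.dcmTagKey(group, elem)]] <- list(vr = vr, value = val)
    if (group == 0x0002 && elem == 0x0000)
      metaEnd <- pos + hdr + len + readBin(val, "integer", size = 4,
                                           endian = "little")
    if (group == 0x0002 && elem == 0x0010) {
      ts <- trimws(rawToChar(val[val != as.raw(0)]))
      if (ts == "1.2.840.10008.1.2") explicit <- FALSE
      else if (ts != "1.2.840.10008.1.2.1")
        .stopf("unsupported transfer syntax %s in %s", ts, path)
    }
    pos <- pos + hdr + len
  }
  elems
}

.dcmStr <- function(elems, key, default = NULL) {
  e <- elems[[key]]
  if (is.null(e)) return(default)
  trimws(rawToChar(e$value[e$value != as.raw(0)]))
}

.dcmNum <- function(elems, key, default = NULL) {
  s <- .dcmStr(elems, key)
  if (is.null(s)) return(default)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

.dcmU16 <- function(elems, key, default = NULL) {
  e <- elems[[key]]
  if (is.null(e)) return(default)
  readBin(e$value, "integer", size = 2, endian = "little", signed = FALSE)
}

.readDicomSlice <- function(path) {
  el <- .parseDicomFile(path)
  rows <- .dcmU16(el, "0028,0010"); cols <- .dcmU16(el, "0028,0011")
  if (is.null(rows) || is.null(cols)) .stopf("missing Rows/Columns: %s", path)
  ps <- .dcmNum(el, "0028,0030")
  ipp <- .dcmNum(el, "0020,0032", default = c(0, 0, 0))
  iop <- .dcmNum(el, "0020,0037", default = c(1, 0, 0, 0, 1, 0))
  if (max(abs(iop - c(1, 0, 0, 0, 1, 0))) > 1e-4)
    .stopf("non-axial orientation unsupported: %s", path)
  slope <- .dcmNum(el, "0028,1053", default = 1)
  icpt <- .dcmNum(el, "0028,1052", default = 0)
  bits <- .dcmU16(el, "0028,0100", default = 16L)
  if (bits != 16L) .stopf("only 16-bit pixel data supported: %s", path)
  rep <- .dcmU16(el, "0028,0103", default = 0L)
  pd <- el[["7FE0,0010"]]
  if (is.null(pd)) .stopf("missing PixelData: %s", path)
  sv <- readBin(pd$value, "integer", n = rows * cols, size = 2,
                endian = "little", signed = rep == 1L)
  hu <- matrix(slope * sv + icpt, nrow = rows, byrow = TRUE) # [y, x]
  list(hu = hu, rows = rows, cols = cols, pixelSpacing = ps, ipp = ipp,
       instance = .dcmStr(el, "0020,0013", default = NA))
}

#' Read an axial DICOM series directory as a CTVolume
#'
#' Files are sorted by slice position; the series must share one frame of
#' reference with equidistant slices, identity in-plane orientation, and a
#' 16-bit monochrome encoding. Rescale slope/intercept is applied to yield
#' Hounsfield units.
#'
#' @param dir directory containing the \code{.dcm} files of one series.
#' @param phase optional respiratory-phase label.
#' @return a \linkS4class{CTVolume}.
#' @export
readDicomSeries <- function(dir, phase = NA_character_) {
  if (!dir.exists(dir)) .stopf("directory not found: %s", dir)
  files <- list.files(dir, pattern = "\\.dcm$", full.names = TRUE,
                      ignore.case = TRUE)
  if (!length(files)) files <- list.files(dir, full.names = TRUE)
  if (length(files) < 2L) .stopf("need >= 2 slices in %s", dir)
  slices <- lapply(files, .readDicomSlice)
  zs <- vapply(slices, function(s) s$ipp[3], numeric(1))
  ord <- order(zs)
  slices <- slices[ord]; zs <- zs[ord]
  dz <- diff(zs)
  if (any(dz <= 0) || (max(dz) - min(dz)) > 1e-3 * mean(dz))
    .stopf("inconsistent slice spacing in %s", dir)
  r1 <- slices[[1]]
  same <- vapply(slices, function(s)
    s$rows == r1$rows && s$cols == r1$cols &&
      isTRUE(all.equal(s$pixelSpacing, r1$pixelSpacing)), logical(1))
  if (!all(same)) .stopf("mixed geometry within series %s", dir)
  arr <- array(0, c(length(slices), r1$rows, r1$cols))
  for (i in seq_along(slices)) arr[i, , ] <- slices[[i]]$hu
  # PixelSpacing is (row, column) = (y, x); IPP is (x, y, z)
  CTVolume(arr,
           spacing = c(mean(dz), r1$pixelSpacing[1], r1$pixelSpacing[2]),
           origin = c(zs[1], r1$ipp[2], r1$ipp[1]),
           phase = phase)
}

.dcmPad <- function(s, nul = FALSE) {
  r <- charToRaw(s)
  if (length(r) %% 2 == 1) r <- c(r, if (nul) as.raw(0) else charToRaw(" "))
  r
}

.dcmElement <- function(group, elem, vr, value) {
  hdr <- writeBin(as.integer(c(group, elem)), raw(), size = 2,
                  endian = "little")
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  if (vr %in% long_vrs) {
    c(hdr, charToRaw(vr), as.raw(c(0, 0)),
      writeBin(length(value), raw(), size = 4, endian = "little"), value)
  } else {
    c(hdr, charToRaw(vr),
      writeBin(length(value), raw(), size = 2, endian = "little"), value)
  }
}

#' Write a synthetic axial DICOM series (testing aid)
#'
#' Emits one explicit-VR little-endian file per slice with the geometry and
#' rescale tags that \code{\link{readDicomSeries}} consumes. Intended for
#' constructing synthetic series in tests and examples; it is not a general
#' DICOM exporter.
#'
#' @param storedValues 3-D integer array \code{(nz, ny, nx)} of stored pixel
#'   values (unsigned 16-bit range).
#' @param dir output directory (created if needed).
#' @param spacing numeric(3) mm \code{(z, y, x)}.
#' @param origin numeric(3) mm \code{(z, y, x)}.
#' @param slope,intercept rescale mapping, \code{HU = slope * SV + intercept}.
#' @return the directory, invisibly.
#' @export
writeDicomSeries <- function(storedValues, dir, spacing = c(2.5, 1.5, 1.5),
                             origin = c(0, 0, 0), slope = 1,
                             intercept = -1024) {
  stopifnot(length(dim(storedValues)) == 3L)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(storedValues)
  sv <- round(storedValues)
  if (any(sv < 0) || any(sv > 65535))
    .stopf("stored values must fit unsigned 16-bit")
  fmtDS <- function(x) paste(sprintf("%g", x), collapse = "\\")
  for (i in seq_len(d[1])) {
    z <- origin[1] + (i - 1) * spacing[1]
    sl <- sv[i, , ]                                   # [y, x]
    pix <- writeBin(as.integer(t(sl)), raw(), size = 2, endian = "little")
    meta <- c(
      .dcmElement(0x0002, 0x0010, "UI",
                  .dcmPad("1.2.840.10008.1.2.1", nul = TRUE)))
    meta <- c(.dcmElement(0x0002, 0x0000, "UL",
                          writeBin(length(meta), raw(), size = 4,
                                   endian = "little")), meta)
    body <- c(
      .dcmElement(0x0008, 0x0060, "CS", .dcmPad("CT")),
      .dcmElement(0x0020, 0x0013, "IS", .dcmPad(as.character(i))),
      .dcmElement(0x0020, 0x0032, "DS",
                  .dcmPad(fmtDS(c(origin[3], origin[2], z)))),
      .dcmElement(0x0020, 0x0037, "DS", .dcmPad(fmtDS(c(1, 0, 0, 0, 1, 0)))),
      .dcmElement(0x0028, 0x0002, "US",
                  writeBin(1L, raw(), size = 2, endian = "little")),
      .dcmElement(0x0028, 0x0004, "CS", .dcmPad("MONOCHROME2")),
      .dcmElement(0x0028, 0x0010, "US",
                  writeBin(d[2], raw(), size = 2, endian = "little")),
      .dcmElement(0x0028, 0x0011, "US",
                  writeBin(d[3], raw(), size = 2, endian = "little")),
      .dcmElement(0x0028, 0x0030, "DS",
                  .dcmPad(fmtDS(c(spacing[2], spacing[3])))),
      .dcmElement(0x0028, 0x0100, "US",
                  writeBin(16L, raw(), size = 2, endian = "little")),
      .dcmElement(0x0028, 0x0101, "US",
                  writeBin(16L, raw(), size = 2, endian = "little")),
      .dcmElement(0x0028, 0x0102, "US",
                  writeBin(15L, raw(), size = 2, endian = "little")),
      .dcmElement(0x0028, 0x0103, "US",
                  writeBin(0L, raw(), size = 2, endian = "little")),
      .dcmElement(0x0028, 0x1052, "DS", .dcmPad(fmtDS(intercept))),
      .dcmElement(0x0028, 0x1053, "DS", .dcmPad(fmtDS(slope))),
      .dcmElement(0x7FE0, 0x0010, "OW", pix))
    con <- file(file.path(dir, sprintf("slice%03d.dcm", i)), "wb")
    writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
    close(con)
  }
  invisible(dir)
}
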