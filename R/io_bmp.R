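# Minimal BMP codec: uncompressed Windows bitmaps, 24/32-bit true colour or
# 8-bit palette, bottom-up or top-down. Written in-package because none of
# the installed raster packages handle BMP. Output is always 24-bit BI_RGB.

read_bmp <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 54 || rawToChar(raw[1:2]) != "BM")
    stop_format("not a BMP file: ", path)
  u16 <- function(i) sum(as.integer(raw[i + 0:1]) * c(1, 256))
  u32 <- function(i) sum(as.integer(raw[i + 0:3]) * 256^(0:3))
  data_offset <- u32(11)
  header_size <- u32(15)
  if (header_size < 40) stop_format("unsupported BMP header (core header)")
  width <- u32(19)
  height_raw <- u32(23)
  top_down <- height_raw > 2^31 - 1
  height <- if (top_down) 2^32 - height_raw else height_raw
  bpp <- u16(29)
  compression <- u32(31)
  if (compression != 0) stop_format("compressed BMP not supported")
  if (!bpp %in% c(8, 24, 32))
    stop_format("unsupported BMP bit depth: ", bpp)

  palette <- NULL
  if (bpp == 8) {
    n_colors <- u32(47)
    if (n_colors == 0) n_colors <- 256
    pal_start <- 14 + header_size
    pal <- matrix(as.integer(raw[pal_start + seq_len(4 * n_colors)]),
                  ncol = 4, byrow = TRUE)  # B,G,R,reserved
    palette <- pal[, 3:1, drop = FALSE] / 255
  }

  bytes_pp <- bpp / 8
  stride <- ((width * bytes_pp + 3) %/% 4) * 4
  px_raw <- raw[data_offset + seq_len(stride * height)]
  rows <- matrix(as.integer(px_raw), nrow = stride)[seq_len(width * bytes_pp), ,
                                                    drop = FALSE]
  # rows: (width*bytes_pp) x height, column = one scanline
  img <- array(0, dim = c(height, width, 3L))
  row_order <- if (top_down) seq_len(height) else rev(seq_len(height))
  if (bpp == 8) {
    idx <- t(rows)[row_order, , drop = FALSE] + 1L  # height x width
    for (ch in 1:3) img[, , ch] <- matrix(palette[idx, ch], height, width)
  } else {
    for (ch in 1:3) {
      # stored as B,G,R(,A): channel ch of RGB sits at byte offset 3-ch
      plane <- rows[seq(3 - ch + 1, by = bytes_pp, length.out = width), ,
                    drop = FALSE]
      img[, , ch] <- t(plane)[row_order, , drop = FALSE] / 255
    }
  }
  img
}

write_bmp <- function(img, path) {
  stopifnot(length(dim(img)) == 3, dim(img)[3] == 3)
  h <- dim(img)[1]; w <- dim(img)[2]
  codes <- array(as.integer(round(pmin(pmax(img, 0), 1) * 255)), dim(img))
  stride <- ((w * 3 + 3) %/% 4) * 4
  pix <- matrix(0L, nrow = stride, ncol = h)
  for (ch in 1:3)  # BGR order, bottom-up rows
    pix[seq(3 - ch + 1, by = 3, length.out = w), ] <- t(codes[rev(seq_len(h)), , ch])
  u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- stride * h
  writeBin(charToRaw("BM"), con)
  u32(54 + data_size); u32(0); u32(54)          # file size, reserved, offset
  u32(40); u32(w); u32(h); u16(1); u16(24)      # BITMAPINFOHEADER
  u32(0); u32(data_size); u32(2835); u32(2835)  # BI_RGB, size, 72 dpi
  u32(0); u32(0)
  writeBin(as.raw(pix), con)
  invisible(path)
}
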