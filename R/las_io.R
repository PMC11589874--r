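# LAS 1.2/1.4 binary point-cloud I/O with extra-bytes attribute records.
#
# The writer emits uncompressed LAS 1.4, point data record format 6, with a
# fixed 0.001 m coordinate scale and per-file offsets at the floor of the
# coordinate minima; pipeline attributes (Reflectance, Deviation, Theta, Phi,
# Range, Label) are stored as named double extra-byte records following the
# RIEGL naming convention. The reader accepts LAS 1.2-1.4 in point formats
# 0, 1 and 6 and matches extra-byte names case-insensitively. LAZ-compressed
# input is detected and rejected with an informative error (no laszip codec
# is bundled); files written by this package are always uncompressed LAS
# regardless of the file extension.

.las_scale <- 0.001

# canonical extra-byte names, column name -> stored name
.las_extra_names <- c(reflectance = "Reflectance", deviation = "Deviation",
                      theta = "Theta", phi_az = "Phi", range = "Range",
                      label = "Label")

.las_column_for <- function(stored) {
  low <- tolower(stored)
  hit <- match(low, tolower(.las_extra_names))
  if (!is.na(hit)) names(.las_extra_names)[hit] else low
}

.r_u16 <- function(con) readBin(con, "integer", 1L, 2L, signed = FALSE,
                                endian = "little")
.r_u32 <- function(con) {
  v <- readBin(con, "integer", 1L, 4L, endian = "little")
  if (v < 0) v + 2^32 else as.double(v)
}
.r_u64 <- function(con) {
  lo <- .r_u32(con)
  hi <- .r_u32(con)
  hi * 2^32 + lo
}
.r_str <- function(con, n) {
  r <- readBin(con, "raw", n)
  rawToChar(r[cummax(as.integer(r != as.raw(0))) > 0 & r != as.raw(0)])
}

.w_u16 <- function(v) writeBin(as.integer(v), raw(), size = 2L,
                               endian = "little")
.w_u32 <- function(v) {
  v <- as.double(v)
  out <- raw(4L * length(v))
  for (i in seq_along(v)) {
    x <- v[i]
    out[(i - 1) * 4 + 1:4] <- as.raw(c(x %% 256, x %/% 256 %% 256,
                                       x %/% 256^2 %% 256, x %/% 256^3 %% 256))
  }
  out
}
.w_u64 <- function(v) c(.w_u32(v %% 2^32), .w_u32(v %/% 2^32))
.w_dbl <- function(v) writeBin(as.double(v), raw(), size = 8L,
                               endian = "little")
.w_str <- function(s, n) {
  r <- charToRaw(s)
  if (length(r) > n) r <- r[seq_len(n)]
  c(r, raw(n - length(r)))
}

# one 192-byte extra-bytes descriptor, data type 10 (double)
.las_eb_descriptor <- function(name) {
  c(raw(2),                      # reserved
    as.raw(10L),                 # data type: double
    raw(1),                      # options: none
    .w_str(name, 32L),
    raw(4),                      # unused
    raw(3 * 8),                  # no_data
    raw(3 * 8), raw(3 * 8),      # min, max
    raw(3 * 8), raw(3 * 8),      # scale, offset
    .w_str("", 32L))             # description
}

#' Write a point cloud to a LAS file
#'
#' Writes uncompressed LAS 1.4 (point record format 6) with 0.001 m coordinate
#' resolution. `intensity`, `return_number` and `number_of_returns` go to the
#' standard LAS fields; all other attribute columns are stored as named
#' double-typed extra-byte records (`Reflectance`, `Deviation`, `Theta`,
#' `Phi`, `Range`, `Label`, plus any custom column under its own name). A
#' read-back equals the input to within half the coordinate quantum.
#'
#' @param cloud a [PointCloud-class].
#' @param path output file path. The bytes written are always uncompressed
#'   LAS; no LAZ codec is bundled.
#' @return `path`, invisibly.
#' @seealso [readPointCloud()]
#' @export
writePointCloud <- function(cloud, path) {
  stopifnot(is(cloud, "PointCloud"))
  validObject(cloud)
  d <- pointData(cloud)
  n <- nrow(d)
  extras <- setdiff(names(d),
                    c("x", "y", "z", "intensity", "return_number",
                      "number_of_returns"))
  n_extra <- length(extras)
  rec_len <- 30L + 8L * n_extra

  off <- if (n) floor(c(min(d$x), min(d$y), min(d$z))) else c(0, 0, 0)
  Xi <- if (n) as.integer(round((d$x - off[1]) / .las_scale)) else integer()
  Yi <- if (n) as.integer(round((d$y - off[2]) / .las_scale)) else integer()
  Zi <- if (n) as.integer(round((d$z - off[3]) / .las_scale)) else integer()

  vlrs <- raw()
  n_vlr <- 0L
  if (n_extra) {
    stored <- unname(.las_extra_names[extras])
    stored[is.na(stored)] <- extras[is.na(stored)]
    payload <- do.call(c, lapply(stored, .las_eb_descriptor))
    vlrs <- c(vlrs, raw(2), .w_str("LASF_Spec", 16L), .w_u16(4L),
              .w_u16(length(payload)), .w_str("extra bytes", 32L), payload)
    n_vlr <- n_vlr + 1L
  }
  if (nzchar(crs(cloud))) {
    payload <- charToRaw(crs(cloud))
    vlrs <- c(vlrs, raw(2), .w_str("plstree", 16L), .w_u16(1L),
              .w_u16(length(payload)), .w_str("crs tag", 32L), payload)
    n_vlr <- n_vlr + 1L
  }
  data_offset <- 375L + length(vlrs)

  rn <- if ("return_number" %in% names(d)) d$return_number else rep(0L, n)
  nr <- if ("number_of_returns" %in% names(d)) d$number_of_returns
        else rep(0L, n)
  by_ret <- vapply(1:15, function(k) sum(rn == k), numeric(1))
  if (n && all(rn == 0)) by_ret[1] <- n

  header <- c(
    charToRaw("LASF"), .w_u16(0L), .w_u16(0L), raw(16),
    as.raw(c(1L, 4L)), .w_str("plstree", 32L), .w_str("plstree R package", 32L),
    .w_u16(1L), .w_u16(2020L),           # fixed creation date: deterministic
    .w_u16(375L), .w_u32(data_offset), .w_u32(n_vlr),
    as.raw(6L), .w_u16(rec_len),
    .w_u32(0L), .w_u32(rep(0L, 5)),      # legacy counts unused for format 6
    .w_dbl(rep(.las_scale, 3)), .w_dbl(off),
    .w_dbl(if (n) c(max(d$x), min(d$x), max(d$y), min(d$y), max(d$z),
                    min(d$z)) else numeric(6)),
    .w_u64(0), .w_u64(0), .w_u32(0L),
    .w_u64(n), do.call(c, lapply(by_ret, .w_u64)))
  stopifnot(length(header) == 375L)

  block <- matrix(as.raw(0), nrow = rec_len, ncol = n)
  if (n) {
    block[1:4, ] <- matrix(writeBin(Xi, raw(), size = 4L, endian = "little"),
                           nrow = 4)
    block[5:8, ] <- matrix(writeBin(Yi, raw(), size = 4L, endian = "little"),
                           nrow = 4)
    block[9:12, ] <- matrix(writeBin(Zi, raw(), size = 4L, endian = "little"),
                            nrow = 4)
    if ("intensity" %in% names(d)) {
      iv <- pmax(0, pmin(65535, round(d$intensity)))
      block[13:14, ] <- matrix(.w_u16(iv), nrow = 2)
    }
    block[15, ] <- as.raw(pmin(15, pmax(0, rn)) + 16 * pmin(15, pmax(0, nr)))
    at <- 31L
    for (nm in extras) {
      block[at:(at + 7L), ] <- matrix(.w_dbl(as.double(d[[nm]])), nrow = 8)
      at <- at + 8L
    }
  }

  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot open '", path,
                                           "' for writing: ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  writeBin(header, con)
  if (length(vlrs)) writeBin(vlrs, con)
  if (n) writeBin(as.vector(block), con)
  invisible(path)
}

# parse the extra-bytes VLR payload into (name, type, size) descriptors
.las_parse_eb <- function(payload) {
  n_desc <- length(payload) %/% 192L
  out <- vector("list", n_desc)
  sizes <- c(1, 1, 2, 2, 4, 4, 8, 8, 4, 8)  # types 1..10 (7/8: 64-bit ints)
  for (i in seq_len(n_desc)) {
    b <- payload[((i - 1) * 192 + 1):(i * 192)]
    type <- as.integer(b[3])
    nm <- rawToChar(b[5:36][b[5:36] != as.raw(0)])
    if (type < 1 || type > 10)
      stop("unsupported extra-bytes data type ", type, " for '", nm, "'")
    out[[i]] <- list(name = nm, type = type, size = sizes[type])
  }
  out
}

.las_read_field <- function(block, rec_len, n, at, size, what, signed = TRUE) {
  idx <- rep((seq_len(n) - 1L) * rec_len, each = size) + (at - 1L) +
    seq_len(size)
  if (what == "byte") return(as.integer(block[idx]))
  readBin(block[idx], what, n = n, size = size,
          signed = if (size < 4) signed else TRUE, endian = "little")
}

#' Read a point cloud from a LAS file
#'
#' Accepts uncompressed LAS 1.2-1.4 in point record formats 0, 1 and 6.
#' Coordinates are descaled to metres; extra-byte attributes are matched by
#' name, case-insensitively, against the conventional `Reflectance`,
#' `Deviation`, `Theta`, `Phi`, `Range` and `Label` records (other names are
#' kept, lower-cased). Return-number fields that are entirely zero (written by
#' tools lacking return information) are treated as absent rather than
#' zero-filled.
#'
#' @param path LAS file path.
#' @param requiredAttrs character vector of attribute column names that must
#'   be present (e.g. `c("reflectance", "deviation")`); a missing one is an
#'   error naming the attribute.
#' @return a [PointCloud-class]; reading a zero-point file warns and returns
#'   an empty cloud.
#' @seealso [writePointCloud()]
#' @export
readPointCloud <- function(path, requiredAttrs = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  if (!identical(rawToChar(readBin(con, "raw", 4L)), "LASF"))
    stop("'", path, "' is not a LAS file (bad signature)")
  invisible(readBin(con, "raw", 20L))           # source, encoding, guid
  ver <- as.integer(readBin(con, "raw", 2L))
  if (ver[1] != 1L || ver[2] < 2L || ver[2] > 4L)
    stop("unsupported LAS version ", ver[1], ".", ver[2])
  invisible(readBin(con, "raw", 64L))           # system id, software
  invisible(readBin(con, "raw", 4L))            # creation date
  header_size <- .r_u16(con)
  data_offset <- .r_u32(con)
  n_vlr <- .r_u32(con)
  pdrf <- as.integer(readBin(con, "raw", 1L))
  if (bitwAnd(pdrf, 128L) != 0L)
    stop("'", path, "' is LAZ-compressed; no laszip codec is available, ",
         "decompress to .las first")
  rec_len <- .r_u16(con)
  n_legacy <- .r_u32(con)
  invisible(readBin(con, "raw", 20L))           # legacy by-return
  scales <- readBin(con, "double", 3L, endian = "little")
  offs <- readBin(con, "double", 3L, endian = "little")
  invisible(readBin(con, "double", 6L, endian = "little"))  # bbox
  n_pts <- n_legacy
  if (ver[2] >= 4L) {
    invisible(readBin(con, "raw", 20L))         # waveform/EVLR pointers
    n_pts <- .r_u64(con)
    invisible(readBin(con, "raw", 120L))        # by-return
  }
  if (!pdrf %in% c(0L, 1L, 6L))
    stop("unsupported LAS point record format ", pdrf)

  # VLRs
  seek(con, header_size)
  eb <- list()
  crs_tag <- ""
  for (v in seq_len(n_vlr)) {
    invisible(readBin(con, "raw", 2L))
    user <- .r_str(con, 16L)
    rec_id <- .r_u16(con)
    len <- .r_u16(con)
    invisible(readBin(con, "raw", 32L))
    payload <- readBin(con, "raw", len)
    if (user == "LASF_Spec" && rec_id == 4L) eb <- .las_parse_eb(payload)
    if (user == "plstree" && rec_id == 1L) crs_tag <- rawToChar(payload)
  }

  base_len <- c(`0` = 20L, `1` = 28L, `6` = 30L)[as.character(pdrf)]
  eb_bytes <- sum(vapply(eb, function(e) e$size, numeric(1)))
  if (rec_len < base_len + eb_bytes)
    stop("point record length ", rec_len, " smaller than declared layout")

  n <- as.integer(n_pts)
  seek(con, data_offset)
  block <- readBin(con, "raw", n * rec_len)
  if (length(block) < n * rec_len)
    stop("truncated LAS file: expected ", n, " point records")

  d <- data.frame(
    x = .las_read_field(block, rec_len, n, 1L, 4L, "integer") * scales[1] +
      offs[1],
    y = .las_read_field(block, rec_len, n, 5L, 4L, "integer") * scales[2] +
      offs[2],
    z = .las_read_field(block, rec_len, n, 9L, 4L, "integer") * scales[3] +
      offs[3])
  d$intensity <- .las_read_field(block, rec_len, n, 13L, 2L, "integer",
                                 signed = FALSE)
  flag <- .las_read_field(block, rec_len, n, 15L, 1L, "byte")
  if (pdrf == 6L) {
    rn <- flag %% 16L
    nr <- flag %/% 16L
  } else {
    rn <- flag %% 8L
    nr <- (flag %/% 8L) %% 8L
  }
  if (n && any(rn != 0L)) {
    d$return_number <- rn
    d$number_of_returns <- nr
  }
  at <- base_len + 1L
  for (e in eb) {
    col <- .las_column_for(e$name)
    d[[col]] <- switch(as.character(e$type),
      `1` = .las_read_field(block, rec_len, n, at, 1L, "byte"),
      `2` = .las_read_field(block, rec_len, n, at, 1L, "integer"),
      `3` = .las_read_field(block, rec_len, n, at, 2L, "integer",
                            signed = FALSE),
      `4` = .las_read_field(block, rec_len, n, at, 2L, "integer"),
      `5` = ,
      `6` = .las_read_field(block, rec_len, n, at, 4L, "integer"),
      `9` = .las_read_field(block, rec_len, n, at, 4L, "double"),
      `10` = .las_read_field(block, rec_len, n, at, 8L, "double"),
      stop("unsupported extra-bytes type ", e$type))
    at <- at + e$size
  }

  missing_attrs <- setdiff(requiredAttrs, names(d))
  if (length(missing_attrs))
    stop("required attribute(s) absent from '", path, "': ",
         paste(missing_attrs, collapse = ", "))
  if (n == 0L) warning("'", path, "' contains zero points")
  PointCloud(d, crs = crs_tag)
}
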