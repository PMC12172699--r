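# Hand-rolled minimal NIfTI-1 writer, used as an independent oracle for
# header arithmetic (scl_slope / scl_inter) and to craft malformed files.
# Writes int16 data with an identity-ish sform.
write_raw_nii <- function(path, data, slope = 1, inter = 0,
                          magic = "n+1") {
  dims <- dim(data)
  stopifnot(length(dims) == 3)
  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(n) writeBin(raw(n), con)
  writeBin(348L, con, size = 4, endian = "little")        # sizeof_hdr
  pad(36)                                                 # through dim_info
  writeBin(as.integer(c(3, dims, 1, 1, 1, 1)), con, size = 2,
           endian = "little")                             # dim[8]
  pad(14)                                                 # intent_p1..code
  writeBin(4L, con, size = 2, endian = "little")          # datatype int16
  writeBin(16L, con, size = 2, endian = "little")         # bitpix
  writeBin(0L, con, size = 2, endian = "little")          # slice_start
  writeBin(c(0, 1, 1, 1, 1, 1, 1, 1), con, size = 4,
           endian = "little")                             # pixdim[8]
  writeBin(352, con, size = 4, endian = "little")         # vox_offset
  writeBin(as.numeric(slope), con, size = 4, endian = "little")
  writeBin(as.numeric(inter), con, size = 4, endian = "little")
  pad(2 + 1 + 1 + 4 + 4 + 4 + 4 + 4 + 4)                  # slice_end..glmin
  pad(80 + 24)                                            # descrip, aux_file
  writeBin(c(0L, 2L), con, size = 2, endian = "little")   # qform, sform code
  writeBin(numeric(6), con, size = 4, endian = "little")  # quaternions
  writeBin(c(1, 0, 0, 0), con, size = 4, endian = "little")  # srow_x
  writeBin(c(0, 1, 0, 0), con, size = 4, endian = "little")  # srow_y
  writeBin(c(0, 0, 1, 0), con, size = 4, endian = "little")  # srow_z
  pad(16)                                                 # intent_name
  writeBin(c(charToRaw(magic), raw(4 - nchar(magic))), con)
  writeBin(raw(4), con)                                   # extension flag
  writeBin(as.integer(data), con, size = 2, endian = "little")
  invisible(path)
}
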