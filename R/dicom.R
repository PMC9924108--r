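#' @include plan-model.R
NULL

## ---- minimal DICOM parser (little endian, explicit or implicit VR) ----
## Covers what an RT Plan needs: nested sequences with defined or
## undefined lengths, and the string/binary VRs used by plan modules.

.u16 <- function(raw, pos) {
    as.integer(raw[pos]) + 256L * as.integer(raw[pos + 1L])
}

.u32 <- function(raw, pos) {
    sum(as.numeric(raw[pos:(pos + 3L)]) * c(1, 256, 65536, 16777216))
}

.UNDEF_LEN <- 4294967295

## VRs whose explicit encoding carries a 2-byte reserved field + 4-byte length
.LONG_VRS <- c("OB", "OW", "OF", "OL", "OD", "SQ", "UN", "UT", "UC", "UR")

## tag -> VR dictionary for implicit-VR files (only tags we consume)
.DICOM_VR <- c(
    "00080016" = "UI", "00080018" = "UI", "00080060" = "CS",
    "300A0002" = "SH", "300A0070" = "SQ", "300C0004" = "SQ",
    "300C0006" = "IS", "300A0086" = "DS", "300A00B0" = "SQ",
    "300A00B6" = "SQ", "300A00B8" = "CS", "300A00BC" = "IS",
    "300A00C0" = "IS", "300A00C2" = "LO", "300A00CE" = "CS",
    "300A010E" = "DS", "300A0110" = "IS", "300A0111" = "SQ",
    "300A0112" = "IS", "300A0114" = "DS", "300A011A" = "SQ",
    "300A011C" = "DS", "300A011E" = "DS", "300A011F" = "CS",
    "300A0134" = "DS", "30020050" = "SQ", "30020051" = "CS",
    "30020052" = "SH")

.decodeValue <- function(vr, bytes) {
    if (length(bytes) == 0L) return(NULL)
    txt <- function() trimws(rawToChar(bytes[bytes != as.raw(0)]))
    switch(vr,
        DS = as.numeric(strsplit(txt(), "\\\\")[[1]]),
        IS = as.integer(strsplit(txt(), "\\\\")[[1]]),
        FL = readBin(bytes, "double", size = 4, n = length(bytes) %/% 4,
                     endian = "little"),
        FD = readBin(bytes, "double", size = 8, n = length(bytes) %/% 8,
                     endian = "little"),
        US = readBin(bytes, "integer", size = 2, n = length(bytes) %/% 2,
                     signed = FALSE, endian = "little"),
        SS = readBin(bytes, "integer", size = 2, n = length(bytes) %/% 2,
                     signed = TRUE, endian = "little"),
        UL = readBin(bytes, "integer", size = 4, n = length(bytes) %/% 4,
                     endian = "little"),
        SL = readBin(bytes, "integer", size = 4, n = length(bytes) %/% 4,
                     endian = "little"),
        UI = , SH = , LO = , CS = , ST = , LT = , PN = , AE = , AS = ,
        DA = , DT = , TM = txt(),
        NULL)
}

## Parse one dataset over raw[start, end); returns list(ds = named list,
## pos = first byte after the dataset).  Stops early at any (FFFE,xxxx)
## delimiter tag, leaving pos on it.
.parseDataset <- function(raw, start, end, explicit) {
    out <- list()
    pos <- start
    while (pos + 7 <= end + 1) {
        g <- .u16(raw, pos)
        e <- .u16(raw, pos + 2L)
        if (g == 0xFFFE) break
        if (explicit) {
            vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
            if (vr %in% .LONG_VRS) {
                len <- .u32(raw, pos + 8L)
                hdr <- 12L
            } else {
                len <- .u16(raw, pos + 6L)
                hdr <- 8L
            }
        } else {
            len <- .u32(raw, pos + 4L)
            hdr <- 8L
            tagKey <- sprintf("%04X%04X", g, e)
            vr <- if (tagKey %in% names(.DICOM_VR)) .DICOM_VR[[tagKey]]
                  else if (len == .UNDEF_LEN) "SQ" else "UN"
        }
        tag <- sprintf("%04X%04X", g, e)
        if (len == .UNDEF_LEN) {
            sq <- .parseSequence(raw, pos + hdr, end, explicit, undef = TRUE)
            val <- sq$items
            pos <- sq$pos
        } else if (vr == "SQ") {
            sq <- .parseSequence(raw, pos + hdr, pos + hdr + len - 1L,
                                 explicit, undef = FALSE)
            val <- sq$items
            pos <- pos + hdr + len
        } else {
            val <- if (len > 0)
                .decodeValue(vr, raw[(pos + hdr):(pos + hdr + len - 1L)])
            else NULL
            pos <- pos + hdr + len
        }
        if (!is.null(val)) out[[tag]] <- val
    }
    list(ds = out, pos = pos)
}

## Parse sequence items over raw[start, end]; undefined-length sequences
## terminate at the (FFFE,E0DD) sequence delimiter.
.parseSequence <- function(raw, start, end, explicit, undef) {
    items <- list()
    pos <- start
    while (pos + 7 <= end + 1) {
        g <- .u16(raw, pos)
        e <- .u16(raw, pos + 2L)
        len <- .u32(raw, pos + 4L)
        if (g == 0xFFFE && e == 0xE0DD) {   # sequence delimiter
            pos <- pos + 8L
            break
        }
        if (!(g == 0xFFFE && e == 0xE000))
            stop("malformed DICOM sequence: expected item tag at byte ", pos)
        if (len == .UNDEF_LEN) {
            r <- .parseDataset(raw, pos + 8L, end, explicit)
            items[[length(items) + 1L]] <- r$ds
            pos <- r$pos
            ## expect item delimiter (FFFE,E00D)
            if (.u16(raw, pos) == 0xFFFE && .u16(raw, pos + 2L) == 0xE00D)
                pos <- pos + 8L
        } else {
            r <- .parseDataset(raw, pos + 8L, pos + 7L + len, explicit)
            items[[length(items) + 1L]] <- r$ds
            pos <- pos + 8L + len
        }
    }
    list(items = items, pos = pos)
}

.readDicomDataset <- function(path) {
    size <- file.size(path)
    raw <- readBin(path, "raw", n = size)
    if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
        stop("not a DICOM file (missing DICM marker): ", path)
    ## file meta group: always explicit VR little endian; (0002,0000)
    ## UL group length tells where the main dataset starts
    if (.u16(raw, 133) != 2L || .u16(raw, 135) != 0L)
        stop("malformed DICOM file meta header: ", path)
    metaLen <- .u32(raw, 141)
    metaStart <- 145L
    meta <- .parseDataset(raw, metaStart, metaStart + metaLen - 1L,
                          explicit = TRUE)$ds
    ts <- meta[["00020010"]]
    explicit <- !identical(ts, "1.2.840.10008.1.2")
    if (!is.null(ts) && !ts %in% c("1.2.840.10008.1.2",
                                   "1.2.840.10008.1.2.1"))
        stop("unsupported DICOM transfer syntax '", ts,
             "' (only little-endian implicit/explicit VR)")
    .parseDataset(raw, metaStart + metaLen, length(raw), explicit)$ds
}

## ---- RT Plan assembly ----

#' Read a DICOM RT Plan
#'
#' Parses a DICOM RT Plan file (little-endian implicit or explicit VR)
#' into a \linkS4class{VMATPlan}: beams from \code{BeamSequence} with
#' per-control-point gantry angle, cumulative meterset weight, MLC bank
#' positions (\code{MLCX}) and jaw positions (\code{X/ASYMX},
#' \code{Y/ASYMY}), with positions carried forward across control points
#' that do not restate them (DICOM convention).  Beam metersets come from
#' the first fraction group's \code{ReferencedBeamSequence}; beams
#' without a positive meterset (setup/QA fields) are skipped.  Cumulative
#' meterset weights are normalized to a final value of 1.
#'
#' @param path path to an RT Plan file (RP*.dcm).
#' @param machineProfile MLC profile name the plan is defined on (see
#'   \code{\link{machineProfiles}}).
#' @param machine alternatively, a full \linkS4class{MachineModel}.
#' @param site site label to attach, default \code{"OTHER"}.
#' @return a \linkS4class{VMATPlan}.
#' @export
readDicomRTPlan <- function(path, machineProfile = "HD120",
                            machine = machineModel(machineProfile),
                            site = "OTHER") {
    ds <- .readDicomDataset(path)
    p <- nLeafPairs(machine)
    bnd <- machine@leafBoundaries

    ## beam number -> meterset from the first fraction group
    muMap <- numeric(0)
    for (fg in ds[["300A0070"]] %||% list())
        for (rb in fg[["300C0004"]] %||% list()) {
            num <- rb[["300C0006"]]
            mu <- rb[["300A0086"]]
            if (!is.null(num) && !is.null(mu))
                muMap[as.character(num)] <- mu
        }

    beamItems <- ds[["300A00B0"]]
    if (is.null(beamItems))
        stop("no BeamSequence in ", path, ": not an RT Plan?")

    beams <- list()
    for (item in beamItems) {
        num <- item[["300A00C0"]]
        name <- item[["300A00C2"]] %||% paste0("beam", num)
        mu <- if (!is.null(num)) muMap[as.character(num)] else NA_real_
        if (is.na(mu) || mu <= 0) next   # setup / QA field
        cps <- item[["300A0111"]]
        if (is.null(cps) || length(cps) < 2L)
            stop("beam '", name, "': fewer than 2 control points")

        n <- length(cps)
        gantry <- cmw <- rep(NA_real_, n)
        bankA <- matrix(NA_real_, n, p)
        bankB <- matrix(NA_real_, n, p)
        jaws <- matrix(NA_real_, n, 4)
        curG <- NA_real_
        curA <- curB <- NULL
        curJ <- c(-200, 200, bnd[1], bnd[p + 1L])
        direction <- "CW"
        energy <- NULL
        for (ci in seq_len(n)) {
            cp <- cps[[ci]]
            if (!is.null(cp[["300A011E"]])) curG <- cp[["300A011E"]]
            if (ci == 1L) {
                rd <- cp[["300A011F"]]
                if (identical(rd, "CC")) direction <- "CCW"
                energy <- cp[["300A0114"]]
            }
            for (bld in cp[["300A011A"]] %||% list()) {
                type <- bld[["300A00B8"]]
                posv <- bld[["300A011C"]]
                if (is.null(type) || is.null(posv)) next
                if (type %in% c("X", "ASYMX")) {
                    curJ[1:2] <- posv[1:2]
                } else if (type %in% c("Y", "ASYMY")) {
                    curJ[3:4] <- posv[1:2]
                } else if (type == "MLCX") {
                    if (length(posv) != 2L * p)
                        stop("beam '", name, "', control point ", ci,
                             ": MLC has ", length(posv),
                             " positions but machine '", machine@name,
                             "' expects ", 2L * p)
                    curA <- posv[seq_len(p)]
                    curB <- posv[seq_len(p) + p]
                }
            }
            if (is.null(curA))
                stop("beam '", name, "', control point ", ci,
                     ": no MLC positions (MLCX) available")
            if (is.null(cp[["300A0134"]]))
                stop("beam '", name, "', control point ", ci,
                     ": missing cumulative meterset weight")
            cmw[ci] <- cp[["300A0134"]]
            gantry[ci] <- curG
            bankA[ci, ] <- curA
            bankB[ci, ] <- curB
            jaws[ci, ] <- curJ
        }
        if (any(diff(cmw) < -1e-9)) {
            bad <- which(diff(cmw) < -1e-9)[1] + 1L
            stop("beam '", name, "', control point ", bad,
                 ": cumulative meterset weight decreases")
        }
        final <- item[["300A010E"]] %||% cmw[n]
        if (final > 0) cmw <- cmw / final
        label <- if (is.null(energy)) "6MV" else {
            fluence <- ""
            pfm <- item[["30020050"]]
            if (!is.null(pfm) && length(pfm) &&
                identical(pfm[[1]][["30020051"]], "NON_STANDARD"))
                fluence <- pfm[[1]][["30020052"]] %||% ""
            if (identical(toupper(fluence), "FFF"))
                sprintf("%gFFF", energy)
            else sprintf("%gMV", energy)
        }
        beams[[length(beams) + 1L]] <-
            arcBeam(name, mu, gantry, cmw, bankA, bankB, jaws,
                    energy = label, direction = direction,
                    normalize = FALSE)
    }
    if (!length(beams))
        stop("no treatment beams with positive meterset in ", path)
    planId <- ds[["300A0002"]] %||% ds[["00080018"]] %||% basename(path)
    vmatPlan(planId, site, machine, beams)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
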