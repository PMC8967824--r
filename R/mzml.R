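# Subset mzML 1.1 support: centroid/profile spectra with float binary
# arrays (32- or 64-bit, zlib or uncompressed, base64), MS levels 1-2,
# scan start time and precursor isolation windows. Anything else --
# Numpress-coded arrays in particular -- is rejected with the offending
# CV term named.

CV_MS_LEVEL        <- "MS:1000511"
CV_SCAN_START      <- "MS:1000016"
CV_ISO_TARGET      <- "MS:1000827"
CV_ISO_LOWER       <- "MS:1000828"
CV_ISO_UPPER       <- "MS:1000829"
CV_ZLIB            <- "MS:1000574"
CV_NO_COMPRESSION  <- "MS:1000576"
CV_FLOAT64         <- "MS:1000523"
CV_FLOAT32         <- "MS:1000521"
CV_MZ_ARRAY        <- "MS:1000514"
CV_INTENSITY_ARRAY <- "MS:1000515"
CV_UNIT_MINUTE     <- "UO:0000031"

cvTable <- function(node) {
    ps <- xml2::xml_find_all(node, ".//cvParam")
    data.frame(accession = xml2::xml_attr(ps, "accession"),
               value = xml2::xml_attr(ps, "value"),
               unitAccession = xml2::xml_attr(ps, "unitAccession"),
               stringsAsFactors = FALSE)
}

decodeBinaryArray <- function(node, specId) {
    cv <- cvTable(node)
    acc <- cv$accession

    size <- if (CV_FLOAT64 %in% acc) 8L
            else if (CV_FLOAT32 %in% acc) 4L
            else NA_integer_
    if (is.na(size)) {
        known <- c(CV_MZ_ARRAY, CV_INTENSITY_ARRAY, CV_ZLIB, CV_NO_COMPRESSION)
        offending <- setdiff(acc, known)
        stopUnsupported(
            "spectrum %s: unsupported binary encoding (CV term%s %s); only 32/64-bit floats are handled",
            specId, if (length(offending) > 1) "s" else "",
            paste(offending, collapse = ", "))
    }
    zlib <- CV_ZLIB %in% acc
    if (!zlib && !(CV_NO_COMPRESSION %in% acc)) {
        offending <- setdiff(acc, c(CV_MZ_ARRAY, CV_INTENSITY_ARRAY,
                                    CV_FLOAT64, CV_FLOAT32))
        stopUnsupported(
            "spectrum %s: unsupported compression (CV term%s %s); only zlib or none are handled",
            specId, if (length(offending) > 1) "s" else "",
            paste(offending, collapse = ", "))
    }

    kind <- if (CV_MZ_ARRAY %in% acc) "mz"
            else if (CV_INTENSITY_ARRAY %in% acc) "intensity"
            else "other"

    txt <- xml2::xml_text(xml2::xml_find_first(node, "./binary"))
    txt <- gsub("[[:space:]]", "", txt)
    bytes <- if (nchar(txt)) jsonlite::base64_dec(txt) else raw(0)
    if (zlib && length(bytes))
        bytes <- tryCatch(.cpp_zlib_inflate(bytes),
                          error = function(e) stopParse(
                              "spectrum %s: zlib inflate of binary array failed (%s)",
                              specId, conditionMessage(e)))
    list(kind = kind,
         values = readBin(bytes, "numeric", size = size,
                          n = length(bytes) %/% size, endian = "little"))
}

parseSpectrumNode <- function(node) {
    specId <- xml2::xml_attr(node, "id")
    if (is.na(specId)) specId <- xml2::xml_attr(node, "index")

    own <- cvTable(node)
    lvRow <- own$value[own$accession == CV_MS_LEVEL]
    if (!length(lvRow))
        stopParse("spectrum %s: no MS level (MS:1000511) cvParam", specId)
    msLevel <- as.integer(lvRow[1])

    scan <- xml2::xml_find_first(node, ".//scanList/scan")
    rt <- NA_real_
    if (!inherits(scan, "xml_missing")) {
        scv <- cvTable(scan)
        i <- which(scv$accession == CV_SCAN_START)
        if (length(i)) {
            rt <- as.numeric(scv$value[i[1]])
            if (identical(scv$unitAccession[i[1]], CV_UNIT_MINUTE))
                rt <- rt * 60
        }
    }
    if (is.na(rt))
        stopParse("spectrum %s: no scan start time (MS:1000016)", specId)

    win <- NULL
    iso <- xml2::xml_find_first(node, ".//precursorList/precursor/isolationWindow")
    if (!inherits(iso, "xml_missing")) {
        icv <- cvTable(iso)
        tgt <- as.numeric(icv$value[icv$accession == CV_ISO_TARGET][1])
        loOff <- as.numeric(icv$value[icv$accession == CV_ISO_LOWER][1])
        hiOff <- as.numeric(icv$value[icv$accession == CV_ISO_UPPER][1])
        if (is.finite(tgt) && is.finite(loOff) && is.finite(hiOff))
            win <- c(tgt - loOff, tgt + hiOff)
    }

    arrays <- list(mz = NULL, intensity = NULL)
    for (bda in xml2::xml_find_all(node, ".//binaryDataArrayList/binaryDataArray")) {
        dec <- decodeBinaryArray(bda, specId)
        if (dec$kind %in% c("mz", "intensity")) arrays[[dec$kind]] <- dec$values
    }
    if (is.null(arrays$mz))
        stopParse("spectrum %s lacks an m/z binary array", specId)
    if (is.null(arrays$intensity))
        stopParse("spectrum %s lacks an intensity binary array", specId)
    if (length(arrays$mz) != length(arrays$intensity))
        stopParse("spectrum %s: m/z and intensity array lengths differ", specId)

    srt <- sortSpectrum(arrays$mz, arrays$intensity)
    Spectrum(mz = srt$mz, intensity = srt$intensity, rt = rt,
             msLevel = msLevel, precursorWindow = if (msLevel == 2L) win else NULL)
}

#' Read a (subset) mzML file
#'
#' Handles mzML 1.1 with base64 binary arrays in 32- or 64-bit IEEE
#' floats, zlib-compressed or plain, MS levels 1 and 2, scan start times
#' in seconds or minutes (normalized to seconds) and precursor isolation
#' windows (target +/- offsets). Unsupported encodings (e.g. Numpress) are
#' rejected naming the CV term. Peak lists are sorted by m/z on read.
#'
#' @param path mzML file path.
#' @return list with `spectra` (list of [Spectrum-class] in file order)
#'   and `source` (provenance: path, spectrum count).
#' @export
readMzml <- function(path) {
    if (!file.exists(path)) stopIO("no such file: %s", path)
    doc <- tryCatch(xml2::read_xml(path),
                    error = function(e) stopParse("malformed XML in %s: %s",
                                                  path, conditionMessage(e)))
    xml2::xml_ns_strip(doc)
    if (!length(xml2::xml_find_all(doc, "//mzML")) &&
        !identical(xml2::xml_name(doc), "mzML"))
        stopParse("%s does not contain an <mzML> element", path)
    nodes <- xml2::xml_find_all(doc, "//spectrumList/spectrum")
    spectra <- lapply(nodes, parseSpectrumNode)
    list(spectra = spectra,
         source = list(path = path, nSpectra = length(spectra)))
}

b64chunk <- function(values, size, zlib) {
    bytes <- writeBin(as.numeric(values), raw(), size = size, endian = "little")
    if (zlib) bytes <- memCompress(bytes, type = "gzip")
    gsub("[\r\n]", "", jsonlite::base64_enc(bytes))
}

xmlEscape <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
}

#' Write spectra to a minimal mzML fixture
#'
#' Emits plain (non-indexed) mzML 1.1 that [readMzml()] and standard
#' parsers accept, with configurable binary encodings so the reader matrix
#' can be exercised.
#'
#' @param spectra list of [Spectrum-class] objects.
#' @param path output file path.
#' @param mzBits 64 (default) or 32 bits per m/z value.
#' @param intensityBits 32 (default) or 64 bits per intensity.
#' @param zlib compress binary arrays with zlib before base64 (default
#'   TRUE).
#' @param rtUnit write scan start times in `"second"` (default) or
#'   `"minute"` (to exercise the reader's unit conversion).
#' @return `path`, invisibly.
#' @export
writeMzmlFixture <- function(spectra, path, mzBits = 64L, intensityBits = 32L,
                             zlib = TRUE, rtUnit = c("second", "minute")) {
    rtUnit <- match.arg(rtUnit)
    if (!(mzBits %in% c(32L, 64L)) || !(intensityBits %in% c(32L, 64L)))
        stopConfig("mzBits and intensityBits must each be 32 or 64")

    bitParam <- function(bits) {
        if (bits == 64)
            '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>'
        else
            '<cvParam cvRef="MS" accession="MS:1000521" name="32-bit float" value=""/>'
    }
    compParam <- if (zlib)
        '<cvParam cvRef="MS" accession="MS:1000574" name="zlib compression" value=""/>'
    else
        '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>'

    out <- character(0)
    emit <- function(...) out[[length(out) + 1]] <<- paste0(...)

    emit('<?xml version="1.0" encoding="utf-8"?>')
    emit('<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">')
    emit('  <cvList count="2">')
    emit('    <cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>')
    emit('    <cv id="UO" fullName="Unit Ontology" URI="https://raw.githubusercontent.com/bio-ontology-research-group/unit-ontology/master/unit.obo"/>')
    emit('  </cvList>')
    emit('  <fileDescription>')
    emit('    <fileContent>')
    emit('      <cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>')
    emit('      <cvParam cvRef="MS" accession="MS:1000580" name="MSn spectrum" value=""/>')
    emit('    </fileContent>')
    emit('  </fileDescription>')
    emit('  <softwareList count="1">')
    emit('    <software id="szdpd" version="0.1.0">')
    emit('      <cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value="szdpd"/>')
    emit('    </software>')
    emit('  </softwareList>')
    emit('  <instrumentConfigurationList count="1">')
    emit('    <instrumentConfiguration id="IC1">')
    emit('      <cvParam cvRef="MS" accession="MS:1000031" name="instrument model" value=""/>')
    emit('    </instrumentConfiguration>')
    emit('  </instrumentConfigurationList>')
    emit('  <dataProcessingList count="1">')
    emit('    <dataProcessing id="DP1">')
    emit('      <processingMethod order="0" softwareRef="szdpd">')
    emit('        <cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/>')
    emit('      </processingMethod>')
    emit('    </dataProcessing>')
    emit('  </dataProcessingList>')
    emit('  <run id="run1" defaultInstrumentConfigurationRef="IC1">')
    emit(sprintf('    <spectrumList count="%d" defaultDataProcessingRef="DP1">',
                 length(spectra)))

    rtUnitAttrs <- if (rtUnit == "second")
        'unitCvRef="UO" unitAccession="UO:0000010" unitName="second"'
    else
        'unitCvRef="UO" unitAccession="UO:0000031" unitName="minute"'

    for (i in seq_along(spectra)) {
        s <- spectra[[i]]
        L <- peaksCount(s)
        emit(sprintf('      <spectrum index="%d" id="scan=%d" defaultArrayLength="%d">',
                     i - 1L, i, L))
        emit(sprintf('        <cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="%d"/>',
                     msLevel(s)))
        emit(sprintf('        <cvParam cvRef="MS" accession="%s" name="%s" value=""/>',
                     if (msLevel(s) == 1L) "MS:1000579" else "MS:1000580",
                     if (msLevel(s) == 1L) "MS1 spectrum" else "MSn spectrum"))
        emit('        <cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>')
        rtVal <- if (rtUnit == "second") rtime(s) else rtime(s) / 60
        emit('        <scanList count="1">')
        emit('          <cvParam cvRef="MS" accession="MS:1000795" name="no combination" value=""/>')
        emit('          <scan>')
        emit(sprintf('            <cvParam cvRef="MS" accession="MS:1000016" name="scan start time" value="%.12g" %s/>',
                     rtVal, rtUnitAttrs))
        emit('          </scan>')
        emit('        </scanList>')
        if (msLevel(s) == 2L) {
            w <- precursorWindow(s)
            tgt <- mean(w)
            emit('        <precursorList count="1">')
            emit('          <precursor>')
            emit('            <isolationWindow>')
            emit(sprintf('              <cvParam cvRef="MS" accession="MS:1000827" name="isolation window target m/z" value="%.12g" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>', tgt))
            emit(sprintf('              <cvParam cvRef="MS" accession="MS:1000828" name="isolation window lower offset" value="%.12g" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>', tgt - w[1]))
            emit(sprintf('              <cvParam cvRef="MS" accession="MS:1000829" name="isolation window upper offset" value="%.12g" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>', w[2] - tgt))
            emit('            </isolationWindow>')
            emit('            <selectedIonList count="1">')
            emit('              <selectedIon>')
            emit(sprintf('                <cvParam cvRef="MS" accession="MS:1000744" name="selected ion m/z" value="%.12g" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>', tgt))
            emit('              </selectedIon>')
            emit('            </selectedIonList>')
            emit('            <activation>')
            emit('              <cvParam cvRef="MS" accession="MS:1000133" name="collision-induced dissociation" value=""/>')
            emit('            </activation>')
            emit('          </precursor>')
            emit('        </precursorList>')
        }
        mzB64 <- b64chunk(mz(s), mzBits %/% 8, zlib)
        inB64 <- b64chunk(intensity(s), intensityBits %/% 8, zlib)
        emit('        <binaryDataArrayList count="2">')
        emit(sprintf('          <binaryDataArray encodedLength="%d">', nchar(mzB64)))
        emit('            ', bitParam(mzBits))
        emit('            ', compParam)
        emit('            <cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value="" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>')
        emit('            <binary>', mzB64, '</binary>')
        emit('          </binaryDataArray>')
        emit(sprintf('          <binaryDataArray encodedLength="%d">', nchar(inB64)))
        emit('            ', bitParam(intensityBits))
        emit('            ', compParam)
        emit('            <cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value="" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>')
        emit('            <binary>', inB64, '</binary>')
        emit('          </binaryDataArray>')
        emit('        </binaryDataArrayList>')
        emit('      </spectrum>')
    }

    emit('    </spectrumList>')
    emit('  </run>')
    emit('</mzML>')

    writeLines(out, path, useBytes = TRUE)
    invisible(path)
}
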