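## DICOM fixtures are written at test time by pydicom (an independent
## implementation of the DICOM encoding), from the package's own JSON
## plan dialect.  plan JSON -> pydicom RT Plan -> readDicomRTPlan()
## closes the loop against an external writer.

dicomWriterScript <- function() {
    path <- file.path(tempdir(), "write_rtplan.py")
    if (file.exists(path)) return(path)
    writeLines(c(
"import json, sys",
"from pydicom.dataset import Dataset, FileDataset, FileMetaDataset",
"from pydicom.uid import ExplicitVRLittleEndian, ImplicitVRLittleEndian, generate_uid, UID",
"",
"def build(plan, ts, variant):",
"    fm = FileMetaDataset()",
"    fm.MediaStorageSOPClassUID = UID('1.2.840.10008.5.1.4.1.1.481.5')",
"    fm.MediaStorageSOPInstanceUID = generate_uid()",
"    fm.TransferSyntaxUID = ts",
"    ds = FileDataset('', {}, file_meta=fm, preamble=b'\\0' * 128)",
"    ds.SOPClassUID = fm.MediaStorageSOPClassUID",
"    ds.SOPInstanceUID = fm.MediaStorageSOPInstanceUID",
"    ds.Modality = 'RTPLAN'",
"    ds.RTPlanLabel = plan['plan_id']",
"    fg = Dataset()",
"    fg.FractionGroupNumber = 1",
"    rbs, beams = [], []",
"    for bi, b in enumerate(plan['beams'], start=1):",
"        rb = Dataset()",
"        rb.ReferencedBeamNumber = bi",
"        rb.BeamMeterset = b['mu']",
"        rbs.append(rb)",
"        bm = Dataset()",
"        bm.BeamNumber = bi",
"        bm.BeamName = b['beam_id']",
"        bm.TreatmentDeliveryType = 'TREATMENT'",
"        cps = []",
"        for ci, cp in enumerate(b['control_points']):",
"            d = Dataset()",
"            d.ControlPointIndex = ci",
"            d.CumulativeMetersetWeight = cp['cmw']",
"            d.GantryAngle = cp['gantry']",
"            if ci == 0:",
"                d.GantryRotationDirection = 'CW' if b['direction'] == 'CW' else 'CC'",
"                d.NominalBeamEnergy = 6",
"            jx = Dataset(); jx.RTBeamLimitingDeviceType = 'ASYMX'",
"            jx.LeafJawPositions = [cp['jaws'][0], cp['jaws'][1]]",
"            jy = Dataset(); jy.RTBeamLimitingDeviceType = 'ASYMY'",
"            jy.LeafJawPositions = [cp['jaws'][2], cp['jaws'][3]]",
"            ml = Dataset(); ml.RTBeamLimitingDeviceType = 'MLCX'",
"            pos = list(cp['bank_a']) + list(cp['bank_b'])",
"            if variant == 'badleafcount':",
"                pos = pos + [0.0] * 40",
"            ml.LeafJawPositions = pos",
"            # jaws stated on the first control point only (carry-forward)",
"            d.BeamLimitingDevicePositionSequence = [jx, jy, ml] if ci == 0 else [ml]",
"            cps.append(d)",
"        bm.NumberOfControlPoints = len(cps)",
"        bm.FinalCumulativeMetersetWeight = b['control_points'][-1]['cmw']",
"        bm.ControlPointSequence = cps",
"        beams.append(bm)",
"    if variant == 'setupbeam':",
"        rb = Dataset()",
"        rb.ReferencedBeamNumber = 99",
"        rb.BeamMeterset = 0",
"        rbs.append(rb)",
"        su = Dataset()",
"        su.BeamNumber = 99",
"        su.BeamName = 'SETUP'",
"        su.TreatmentDeliveryType = 'SETUP'",
"        beams.append(su)",
"    fg.ReferencedBeamSequence = rbs",
"    ds.FractionGroupSequence = [fg]",
"    ds.BeamSequence = beams",
"    return ds",
"",
"plan_json, out, syntax, variant = sys.argv[1:5]",
"with open(plan_json) as fh:",
"    plan = json.load(fh)",
"ts = ExplicitVRLittleEndian if syntax == 'explicit' else ImplicitVRLittleEndian",
"ds = build(plan, ts, variant)",
"ds.save_as(out, enforce_file_format=True)"
    ), path)
    path
}

## Round positions so the decimal-string (DS) DICOM encoding is exact.
roundPlan <- function(plan) {
    plan@beams <- lapply(plan@beams, function(b) {
        b@bankA <- round(b@bankA, 2)
        b@bankB <- round(b@bankB, 2)
        b@bankB <- pmax(b@bankB, b@bankA)
        b@jaws <- round(b@jaws, 2)
        b@gantry <- round(b@gantry, 2)
        cmw <- round(b@cmw, 6)
        cmw[1] <- 0
        cmw[length(cmw)] <- 1
        b@cmw <- cummax(cmw)
        b@beamMu <- round(b@beamMu, 3)
        b
    })
    plan
}

writeDicomFixture <- function(plan, out, syntax = "explicit",
                              variant = "none") {
    planJson <- tempfile(fileext = ".json")
    writePlanJSON(plan, planJson)
    res <- system2("python",
                   c(dicomWriterScript(), planJson, out, syntax, variant),
                   stdout = TRUE, stderr = TRUE)
    if (!file.exists(out))
        stop("pydicom fixture writer failed: ", paste(res, collapse = "\n"))
    out
}
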