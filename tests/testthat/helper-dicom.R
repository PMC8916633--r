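# Writes a tiny synthetic DICOM series with pydicom (independent of the
# package's own DICOM reader). 4 axial slices, 16 x 16, RescaleIntercept
# -1024, soft kernel; one marker voxel (stored 24 -> -1000 HU) at row 3,
# col 5 (0-based) of every slice.

write_pydicom_series <- function(dir, drop_middle = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  script <- sprintf('
import os, numpy as np, pydicom
from pydicom.dataset import Dataset, FileMetaDataset
from pydicom.uid import ExplicitVRLittleEndian, generate_uid
outdir = %s
drop = %s
for k in range(4):
    if drop and k == 2:
        continue
    ds = Dataset()
    ds.SOPClassUID = "1.2.840.10008.5.1.4.1.1.2"
    ds.SOPInstanceUID = generate_uid()
    ds.Modality = "CT"
    ds.Rows = 16; ds.Columns = 16
    ds.BitsAllocated = 16; ds.BitsStored = 16; ds.HighBit = 15
    ds.PixelRepresentation = 0; ds.SamplesPerPixel = 1
    ds.PhotometricInterpretation = "MONOCHROME2"
    ds.PixelSpacing = [0.7, 0.6]
    ds.ImagePositionPatient = [-5.0, -4.0, float(k)]
    ds.ImageOrientationPatient = [1, 0, 0, 0, 1, 0]
    ds.RescaleSlope = 1; ds.RescaleIntercept = -1024
    ds.ConvolutionKernel = "SOFT"
    arr = np.full((16, 16), 1124, dtype=np.uint16)
    arr[3, 5] = 24
    ds.PixelData = arr.tobytes()
    fm = FileMetaDataset()
    fm.TransferSyntaxUID = ExplicitVRLittleEndian
    fm.MediaStorageSOPClassUID = ds.SOPClassUID
    fm.MediaStorageSOPInstanceUID = ds.SOPInstanceUID
    ds.file_meta = fm
    ds.save_as(os.path.join(outdir, "s%%d.dcm" %% k),
               enforce_file_format=True)
', deparse(dir), if (drop_middle) "True" else "False")
  status <- system2("python", c("-c", shQuote(script)),
                    stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(status, "status")))
    stop("pydicom fixture writer failed: ", paste(status, collapse = "\n"))
  invisible(dir)
}
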