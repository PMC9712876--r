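#!/usr/bin/env Rscript
# Threshold-segmentation stub plugin. Communicates with the host purely
# through files in the exchange directory (single argument): reads
# image.nii.gz + params.json, writes mask.nii.gz. Deliberately does not use
# the host package, proving the loose-coupling contract.
args <- commandArgs(trailingOnly = TRUE)
if (length(args) != 1L) stop("usage: threshold_plugin.R <workdir>")
wd <- args[1]

params <- jsonlite::fromJSON(file.path(wd, "params.json"))
threshold <- if (!is.null(params$threshold)) params$threshold else 100
direction <- if (!is.null(params$direction)) params$direction else "above"

img <- RNifti::readNifti(file.path(wd, "image.nii.gz"))
mask <- if (identical(direction, "above")) img > threshold else img < threshold
out <- RNifti::asNifti(array(as.integer(mask), dim(img)), reference = img)
RNifti::writeNifti(out, file.path(wd, "mask.nii.gz"))
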