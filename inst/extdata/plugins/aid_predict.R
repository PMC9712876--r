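#!/usr/bin/env Rscript
# External prediction program for the iterative-annotation loop: loads
# model.json, thresholds each staged image with the threshold of its
# nearest-background training image, writes prd_NNN.nii.gz.
args <- commandArgs(trailingOnly = TRUE)
wd <- args[1]
params <- jsonlite::fromJSON(file.path(wd, "params.json"))
model <- jsonlite::fromJSON(file.path(wd, "model.json"))

for (i in seq_len(params$n)) {
  nii <- RNifti::readNifti(file.path(wd, sprintf("img_%03d.nii.gz", i)))
  j <- which.min(abs(median(as.numeric(nii)) - model$bg_levels))
  pred <- array(as.integer(as.numeric(nii) > model$thresholds[j]), dim(nii))
  RNifti::writeNifti(RNifti::asNifti(pred, reference = nii),
                     file.path(wd, sprintf("prd_%03d.nii.gz", i)))
}
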