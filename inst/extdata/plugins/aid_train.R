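#!/usr/bin/env Rscript
# External training program for the iterative-annotation loop: reads labeled
# pairs (img_NNN.nii.gz / msk_NNN.nii.gz) from the exchange directory and
# writes model.json with one (background level, threshold) pair per training
# image. Independent of the host package: files in, files out.
args <- commandArgs(trailingOnly = TRUE)
wd <- args[1]
params <- jsonlite::fromJSON(file.path(wd, "params.json"))
n <- params$n

bg_levels <- numeric(n)
thresholds <- numeric(n)
for (i in seq_len(n)) {
  img <- as.numeric(RNifti::readNifti(file.path(wd, sprintf("img_%03d.nii.gz", i))))
  msk <- as.numeric(RNifti::readNifti(file.path(wd, sprintf("msk_%03d.nii.gz", i)))) != 0
  bg_levels[i] <- median(img)
  thresholds[i] <- (mean(img[msk]) + mean(img[!msk])) / 2
}
writeLines(jsonlite::toJSON(list(bg_levels = bg_levels,
                                 thresholds = thresholds), digits = NA),
           file.path(wd, "model.json"))
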