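#!/bin/sh
# Identity stub plugin: copies every staged input to the corresponding
# expected output, touching nothing else. Written as a plain shell script to
# demonstrate that the disk-exchange protocol needs no in-process linkage
# and no particular language.
set -e
wd="$1"
cd "$wd"
cp image.nii.gz out_image.nii.gz
cp mesh.ply out_mesh.ply
cp annotation.json out_annotation.json
# sidecar files referenced inside the annotation JSON keep their relative
# names and already sit in this directory, so nothing else to do
exit 0
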