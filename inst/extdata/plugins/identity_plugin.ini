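; Identity plugin: returns its inputs untouched. Used to verify round-trip
; fidelity of the disk exchange (images bit-exact, coordinates to 1e-9 mm).

[module]
name = identity
type = analysis
program = identity_plugin.sh

[input.image]
kind = image
required = true

[input.mesh]
kind = mesh
required = true

[input.annotation]
kind = annotation
required = true

[output.out_image]
kind = image

[output.out_mesh]
kind = mesh

[output.out_annotation]
kind = annotation
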