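; Threshold-segmentation extension module: the canonical minimal plugin.
; The program receives the exchange directory as its single argument, reads
; image.nii.gz and params.json, and writes mask.nii.gz.

[module]
name = threshold_demo
type = segmentation
program = threshold_plugin.R

[input.image]
kind = image
required = true

[input.threshold]
kind = number
required = false
default = 100

[input.direction]
kind = choice
required = false
default = above
choices = above,below

[output.mask]
kind = mask

[widget.1]
widget = explanatory_text
label = Label voxels above/below an intensity threshold inside the image.

[widget.2]
widget = text_box
label = Threshold
binds = threshold

[widget.3]
widget = drop_menu
label = Direction
binds = direction

[widget.4]
widget = press_button
label = Calculate
binds = run
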