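# Study-condition presets for the eight-lesion panel.  theta and the
# T->C-dominated spectra are plausible defaults chosen once (the readout
# of these lesions is an exclusive T->C transition); the mixing ratios
# encode the experimental design: 2:1 for the well-bypassed straight
# chains, 5:1 for the poorly bypassed branched alkyl groups.
Me:
  theta: 0.85
  spectrum: {f_T: 0.35, f_C: 0.65, f_A: 0.0, f_G: 0.0}
  r_lesion: 2
  r_control: 1
Et:
  theta: 0.80
  spectrum: {f_T: 0.50, f_C: 0.50, f_A: 0.0, f_G: 0.0}
  r_lesion: 2
  r_control: 1
nPr:
  theta: 0.75
  spectrum: {f_T: 0.60, f_C: 0.40, f_A: 0.0, f_G: 0.0}
  r_lesion: 2
  r_control: 1
nBu:
  theta: 0.70
  spectrum: {f_T: 0.65, f_C: 0.35, f_A: 0.0, f_G: 0.0}
  r_lesion: 2
  r_control: 1
iPr:
  theta: 0.40
  spectrum: {f_T: 0.70, f_C: 0.30, f_A: 0.0, f_G: 0.0}
  r_lesion: 5
  r_control: 1
iBu:
  theta: 0.40
  spectrum: {f_T: 0.70, f_C: 0.30, f_A: 0.0, f_G: 0.0}
  r_lesion: 5
  r_control: 1
sBu_S:
  theta: 0.05
  spectrum: {f_T: 0.75, f_C: 0.25, f_A: 0.0, f_G: 0.0}
  r_lesion: 5
  r_control: 1
sBu_R:
  theta: 0.05
  spectrum: {f_T: 0.75, f_C: 0.25, f_A: 0.0, f_G: 0.0}
  r_lesion: 5
  r_control: 1
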