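# Analysis layout for the 38-channel 10-20 montage:
# 8 midline electrodes, six lateral ROIs (region x hemisphere, 4 sites each),
# and the mastoid reference pair.
midline: [FPz, Fz, FCz, Cz, CPz, Pz, POz, Oz]
rois:
  left anterior:   [F7, F3, FT7, FC3]
  right anterior:  [F4, F8, FC4, FT8]
  left central:    [T7, C3, TP7, CP3]
  right central:   [C4, T8, CP4, TP8]
  left posterior:  [P7, P3, PO7, PO5]
  right posterior: [P4, P8, PO6, PO8]
mastoids: [M1, M2]
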