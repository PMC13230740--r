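# Example fluidic run specification (schema version 1).
# A 3-round sequential smFISH program: strip+hybridize from a per-round
# plate well, incubate, wash from a syringe, image; DAPI staining in
# round 1 only.
n_rounds: 3
buffers:
  wash:    {kind: syringe, address: 1}
  imaging: {kind: syringe, address: 2}
  dapi:    {kind: syringe, address: 3}
  hyb:     {kind: plate,   address: "A{round}"}
steps:
  - {id: hyb,     action: flush, buffer: hyb, volume_ml: 0.5,
     rate_ml_per_min: 0.5}
  - {id: inc_hyb, action: incubate, incubate_s: 600}
  - {id: wash,    action: flush, buffer: wash, volume_ml: 1.0,
     rate_ml_per_min: 1.0}
  - {id: stain,   action: flush, buffer: dapi, volume_ml: 0.3,
     rate_ml_per_min: 0.5, rounds: [1]}
  - {id: img_buf, action: flush, buffer: imaging, volume_ml: 0.8,
     rate_ml_per_min: 1.0}
  - {id: image,   action: image}
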