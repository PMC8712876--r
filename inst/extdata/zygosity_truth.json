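{
  "description": "Expected hybrid Rhesus box status and diploid genotype string for the nine diploid combinations of intact, deletion and variant (c.336-1G>A) haplotypes. The hybrid box is the deletion discriminator: a homozygous-intact genome never yields the hybrid product, so RHD+/RHD+ and RHD+/RHD- are separable.",
  "cases": [
    {"hapA": "intact",   "hapB": "intact",   "hybrid_box": false, "diploid_call": "RHD+/RHD+"},
    {"hapA": "intact",   "hapB": "deletion", "hybrid_box": true,  "diploid_call": "RHD+/RHD-"},
    {"hapA": "intact",   "hapB": "variant",  "hybrid_box": false, "diploid_call": "RHD+/336-1G>A"},
    {"hapA": "deletion", "hapB": "intact",   "hybrid_box": true,  "diploid_call": "RHD+/RHD-"},
    {"hapA": "deletion", "hapB": "deletion", "hybrid_box": true,  "diploid_call": "RHD-/RHD-"},
    {"hapA": "deletion", "hapB": "variant",  "hybrid_box": true,  "diploid_call": "RHD-/336-1G>A"},
    {"hapA": "variant",  "hapB": "intact",   "hybrid_box": false, "diploid_call": "RHD+/336-1G>A"},
    {"hapA": "variant",  "hapB": "deletion", "hybrid_box": true,  "diploid_call": "RHD-/336-1G>A"},
    {"hapA": "variant",  "hapB": "variant",  "hybrid_box": false, "diploid_call": "336-1G>A/336-1G>A"}
  ]
}
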