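{
  "wells": {
    "1": "RHD exon 1 presence",
    "2": "RHD exon 3 presence (acceptor-spanning)",
    "3": "RHD exon 5 presence",
    "4": "RHD exon 7 presence",
    "5": "c.1227G allele-specific",
    "6": "c.1227A allele-specific",
    "7": "hybrid Rhesus box (RHD deletion)",
    "8": "c.845A allele-specific (weak D15)"
  },
  "classes": {
    "RHD_positive":  {"1": "+", "2": "+", "3": "+", "4": "+", "5": "+", "6": "-", "7": "*", "8": "-"},
    "RHD_deletion":  {"1": "-", "2": "-", "3": "-", "4": "-", "5": "-", "6": "-", "7": "+", "8": "-"},
    "RHD_CE_2_9_D":  {"1": "+", "2": "-", "3": "-", "4": "-", "5": "-", "6": "-", "7": "*", "8": "-"},
    "DVa_Hus":       {"1": "+", "2": "+", "3": "-", "4": "+", "5": "+", "6": "-", "7": "*", "8": "-"},
    "DVI_III":       {"1": "+", "2": "-", "3": "-", "4": "+", "5": "+", "6": "-", "7": "*", "8": "-"},
    "weakD15":       {"1": "+", "2": "+", "3": "+", "4": "+", "5": "+", "6": "-", "7": "*", "8": "+"},
    "DEL_1227A_hom": {"1": "+", "2": "+", "3": "+", "4": "+", "5": "-", "6": "+", "7": "-", "8": "-"},
    "DEL_1227A_het": {"1": "+", "2": "+", "3": "+", "4": "+", "5": "*", "6": "+", "7": "+", "8": "-"}
  },
  "notes": [
    "Wells are read as specific-band present (+), absent (-), or uninformative (*).",
    "The hybrid-box well (7) is wildcarded for classes that can occur with or without a deletion haplotype in trans.",
    "DEL_1227A_het requires both the 1227A well and the hybrid-box well: the heterozygote call is only issued when a second, deletion-class allele is evidenced. A 1227A allele over an intact RHD haplotype matches no signature and is reported undetectable.",
    "The three point-mutation alleles (c.3G>A, c.340C>T, c.336-1G>A) extinguish the exon-1 or acceptor-spanning exon-3 presence well and therefore match no signature: they fall through to the sequencing tier."
  ]
}
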