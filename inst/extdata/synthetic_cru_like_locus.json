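{
  "name": "synthetic_cru_like",
  "amplicon": "TACTAACCTCAAAAAATACCCGTTATCATGTATGGGATAGGTCAATGACATTTAGGAACGTGGCTCTCTAAGTTGTCACACGAAGGCTTTGTAACTCAAAAAAACGCGGTTCCGCTCGGCAAGAGAAGTGAAATCCAGTGCCTTGAAAGGGTAATTGCCATCATCGATTGAGTTATCTTGTGCTAAAGTAGCATTGATAGACCACTGTGGCGAAGCCGTAGGCTTCAGTCAGAAGTTCCACCTGGACACGTGGTACTGCAGCTGGACGAGTGATCTATTCAAGCGACTGAACATCGTCTACTTACAATGCAGCGTGGGGAGGGCACATTTGGTGTCGGTGAGGGCGACAAAGTCGCACTGATATAAGATGAAAAGCAGTGCTCTAAGGCACAAGAGCACCGTACCGTCGATCTTTACCGGGTCGGATCTGGTGCGCCCTCCGAGAAAAAATTGTCGCTGTTGCTACATTTTCCGTTGACG",
  "protospacer": {
    "start": 230,
    "end": 250,
    "strand": "+"
  },
  "pam": {
    "start": 250,
    "end": 253
  },
  "enzyme": {
    "name": "PstI",
    "recognition": "CTGCAG"
  },
  "primer_fwd": "TACTAACCTCAAAAAATACC",
  "primer_rev": "CGTCAACGGAAAATGTAGCA",
  "cut_pos": 247
}
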