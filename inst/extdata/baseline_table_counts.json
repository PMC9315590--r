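{
  "comment": "Printed group counts and summaries of the reference 92-patient cohort (rows: poor n=42, good n=50). Group sizes follow from the treatment-row sums 5+9+1+27 and 3+13+2+32.",
  "tables": {
    "gender": {"levels": ["male", "female"], "counts": [[30, 12], [31, 19]]},
    "onset": {"levels": ["<6h", "6-24h", ">24h"], "counts": [[17, 11, 14], [15, 8, 27]]},
    "treatment": {"levels": ["thrombolysis", "endovascular", "bridging", "conservative"], "counts": [[5, 9, 1, 27], [3, 13, 2, 32]]},
    "artery": {"levels": ["ICA", "MCA", "ICA+MCA", "ICA+MCA+ACA"], "counts": [[3, 28, 10, 1], [9, 36, 3, 0]]},
    "toast": {"levels": ["LAA", "CE", "SOE"], "counts": [[25, 15, 2], [38, 9, 3]]},
    "hemorrhage": {"levels": ["yes", "no"], "counts": [[13, 29], [6, 44]]}
  },
  "age": {
    "poor": {"n": 42, "mean": 69.45, "sd": 14.05},
    "good": {"n": 50, "mean": 63.54, "sd": 12.82}
  }
}
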