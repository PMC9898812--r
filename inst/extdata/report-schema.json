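{
  "type": "object",
  "required": ["software", "seed", "category_breakdown", "distances",
               "activity", "throughput"],
  "properties": {
    "software": {
      "type": "object",
      "required": ["package", "version"],
      "properties": {
        "package": {"type": "string"},
        "version": {"type": "string"}
      }
    },
    "seed": {"type": ["number", "null"]},
    "category_breakdown": {
      "type": ["object", "null"],
      "required": ["n_input", "rows"],
      "properties": {
        "n_input": {"type": "number"},
        "rows": {"type": "array"}
      }
    },
    "distances": {
      "type": ["object", "null"],
      "required": ["n", "min", "max", "percentile_95", "median",
                   "ci_low", "ci_high", "ci_reliable", "B", "seed"],
      "properties": {
        "n": {"type": "number"},
        "min": {"type": "number"},
        "max": {"type": "number"},
        "percentile_95": {"type": "number"},
        "median": {"type": "number"},
        "ci_low": {"type": "number"},
        "ci_high": {"type": "number"},
        "ci_reliable": {"type": "boolean"},
        "B": {"type": "number"},
        "seed": {"type": "number"}
      }
    },
    "activity": {
      "type": "object",
      "required": ["transcriptional_cis_regulatory", "five_prime_UTR",
                   "three_prime_UTR"],
      "properties": {
        "transcriptional_cis_regulatory": {"type": ["object", "null"]},
        "five_prime_UTR": {"type": ["object", "null"]},
        "three_prime_UTR": {"type": ["object", "null"]},
        "intron": {"type": ["object", "null"]},
        "downstream": {"type": ["object", "null"]}
      }
    },
    "throughput": {
      "type": "object",
      "required": ["forward_genetics", "crispr", "reporter"],
      "properties": {
        "forward_genetics": {"type": ["object", "null"]},
        "crispr": {"type": ["object", "null"]},
        "reporter": {"type": ["object", "null"]}
      }
    }
  }
}
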