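{
  "name": "toy-bta",
  "description": "Small synthetic Bos-taurus-style pathway library: the less extensively annotated counterpart of toy-hsa, lacking the aminoacyl-tRNA biosynthesis, arginine and proline metabolism, and lysine degradation pathways.",
  "synonyms": {
    "TMAO": "trimethylamine N-oxide",
    "betaine/TMAO": "betaine",
    "3HB": "3-hydroxybutyrate",
    "beta-hydroxybutyrate": "3-hydroxybutyrate",
    "TMA": "trimethylamine",
    "D-glucose": "glucose",
    "L-lysine": "lysine",
    "L-alanine": "alanine",
    "L-glutamate": "glutamate",
    "L-valine": "valine",
    "lactic acid": "lactate",
    "L-lactate": "lactate"
  },
  "pathways": [
    {
      "name": "Biotin metabolism",
      "compounds": [
        "biotin",
        "biocytin",
        "lysine"
      ],
      "edges": [
        [
          "lysine",
          "biocytin"
        ],
        [
          "biocytin",
          "biotin"
        ]
      ]
    },
    {
      "name": "Cyanoamino acid metabolism",
      "compounds": [
        "glycine",
        "serine",
        "asparagine",
        "aspartate"
      ],
      "edges": [
        [
          "serine",
          "glycine"
        ],
        [
          "asparagine",
          "aspartate"
        ]
      ]
    },
    {
      "name": "D-Glutamine and D-glutamate metabolism",
      "compounds": [
        "glutamate",
        "glutamine",
        "D-glutamate",
        "D-glutamine"
      ],
      "edges": [
        [
          "glutamine",
          "glutamate"
        ],
        [
          "glutamate",
          "D-glutamate"
        ],
        [
          "glutamine",
          "D-glutamine"
        ]
      ]
    },
    {
      "name": "Galactose metabolism",
      "compounds": [
        "galactose",
        "glucose",
        "lactose",
        "myo-inositol",
        "sorbitol",
        "glucose-6-phosphate"
      ],
      "edges": [
        [
          "lactose",
          "galactose"
        ],
        [
          "lactose",
          "glucose"
        ],
        [
          "galactose",
          "glucose"
        ],
        [
          "glucose",
          "glucose-6-phosphate"
        ],
        [
          "glucose",
          "sorbitol"
        ],
        [
          "galactose",
          "myo-inositol"
        ]
      ]
    },
    {
      "name": "Glycine, serine and threonine metabolism",
      "compounds": [
        "glycine",
        "serine",
        "threonine",
        "betaine",
        "choline",
        "sarcosine",
        "creatine"
      ],
      "edges": [
        [
          "choline",
          "betaine"
        ],
        [
          "betaine",
          "sarcosine"
        ],
        [
          "sarcosine",
          "glycine"
        ],
        [
          "serine",
          "glycine"
        ],
        [
          "threonine",
          "glycine"
        ],
        [
          "glycine",
          "creatine"
        ],
        [
          "glycine",
          "serine"
        ]
      ]
    },
    {
      "name": "Methane metabolism",
      "compounds": [
        "methanol",
        "formaldehyde",
        "formate",
        "methane",
        "trimethylamine",
        "trimethylamine N-oxide",
        "carbon dioxide"
      ],
      "edges": [
        [
          "trimethylamine N-oxide",
          "trimethylamine"
        ],
        [
          "trimethylamine",
          "methanol"
        ],
        [
          "methanol",
          "formaldehyde"
        ],
        [
          "formaldehyde",
          "formate"
        ],
        [
          "formate",
          "carbon dioxide"
        ],
        [
          "formate",
          "methane"
        ],
        [
          "methanol",
          "methane"
        ]
      ]
    },
    {
      "name": "Nitrogen metabolism",
      "compounds": [
        "glutamate",
        "glutamine",
        "glycine",
        "ammonia",
        "nitrate"
      ],
      "edges": [
        [
          "nitrate",
          "ammonia"
        ],
        [
          "ammonia",
          "glutamine"
        ],
        [
          "glutamine",
          "glutamate"
        ],
        [
          "glutamate",
          "glycine"
        ]
      ]
    },
    {
      "name": "Synthesis and degradation of ketone bodies",
      "compounds": [
        "acetoacetate",
        "3-hydroxybutyrate",
        "acetone",
        "acetyl-CoA"
      ],
      "edges": [
        [
          "acetyl-CoA",
          "acetoacetate"
        ],
        [
          "acetoacetate",
          "3-hydroxybutyrate"
        ],
        [
          "acetoacetate",
          "acetone"
        ]
      ]
    }
  ],
  "background_compounds": [
    "pyruvate",
    "citrate",
    "succinate",
    "fumarate",
    "malate",
    "2-oxoglutarate",
    "isoleucine",
    "leucine",
    "phenylalanine",
    "tyrosine",
    "tryptophan",
    "methionine",
    "histidine",
    "cysteine",
    "arginine-phosphate",
    "taurine",
    "hypotaurine",
    "carnitine",
    "acetylcarnitine",
    "choline-phosphate",
    "glycerol",
    "glycerol-3-phosphate",
    "fructose",
    "mannose",
    "ribose",
    "xylose",
    "maltose",
    "sucrose",
    "urea",
    "uric acid",
    "hippurate",
    "allantoin",
    "dimethylamine",
    "dimethylglycine",
    "ethanol",
    "ethanolamine",
    "glutathione",
    "inosine",
    "hypoxanthine",
    "xanthine",
    "uridine",
    "cytidine",
    "nicotinamide",
    "pantothenate",
    "pyridoxine",
    "ascorbate",
    "oxaloacetate",
    "acetaldehyde"
  ]
}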