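{
  "name": "toy-hsa",
  "description": "Small synthetic Homo-sapiens-style pathway library for over-representation and topology analysis. Pathway names follow the KEGG naming convention; compound sets and directed reaction edges are reduced toy versions sufficient to exercise enrichment and out-degree-centrality impact scoring.",
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
      "name": "Aminoacyl-tRNA biosynthesis",
      "compounds": [
        "glycine",
        "alanine",
        "lysine",
        "glutamate",
        "valine",
        "serine",
        "threonine",
        "proline",
        "glutamine",
        "aminoacyl-tRNA"
      ],
      "edges": [
        [
          "glycine",
          "aminoacyl-tRNA"
        ],
        [
          "alanine",
          "aminoacyl-tRNA"
        ],
        [
          "lysine",
          "aminoacyl-tRNA"
        ],
        [
          "glutamate",
          "aminoacyl-tRNA"
        ],
        [
          "valine",
          "aminoacyl-tRNA"
        ],
        [
          "serine",
          "aminoacyl-tRNA"
        ],
        [
          "threonine",
          "aminoacyl-tRNA"
        ],
        [
          "proline",
          "aminoacyl-tRNA"
        ],
        [
          "glutamine",
          "aminoacyl-tRNA"
        ]
      ]
    },
    {
      "name": "Arginine and proline metabolism",
      "compounds": [
        "arginine",
        "ornithine",
        "proline",
        "creatine",
        "creatinine",
        "glutamate"
      ],
      "edges": [
        [
          "arginine",
          "ornithine"
        ],
        [
          "ornithine",
          "proline"
        ],
        [
          "glutamate",
          "proline"
        ],
        [
          "arginine",
          "creatine"
        ],
        [
          "creatine",
          "creatinine"
        ]
      ]
    },
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
      "name": "Lysine degradation",
      "compounds": [
        "lysine",
        "saccharopine",
        "2-aminoadipate",
        "glutaryl-CoA"
      ],
      "edges": [
        [
          "lysine",
          "saccharopine"
        ],
        [
          "saccharopine",
          "2-aminoadipate"
        ],
        [
          "2-aminoadipate",
          "glutaryl-CoA"
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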