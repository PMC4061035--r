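{
  "name": "ovine-plasma-default",
  "description": "Synthetic 1H NMR peak library for the ovine plasma metabolite panel. Chemical shifts follow standard plasma assignments (HMDB/BMRB conventions); multiplets are reduced to line offsets and relative heights; linewidths are Lorentzian FWHM in ppm.",
  "metabolites": [
    {
      "name": "glucose",
      "synonyms": ["D-glucose"],
      "resonances": [
        {"center": 5.233, "offsets": [-0.0076, 0], "heights": [0.4, 0.6], "fwhm": 0.003, "protons": 1},
        {"center": 3.475, "offsets": [0], "heights": [1], "fwhm": 0.008, "protons": 2},
        {"center": 3.89, "offsets": [0], "heights": [1], "fwhm": 0.008, "protons": 1}
      ]
    },
    {
      "name": "lactate",
      "synonyms": ["L-lactate", "lactic acid"],
      "resonances": [
        {"center": 1.33, "offsets": [-0.0068, 0.0068], "heights": [0.5, 0.5], "fwhm": 0.003, "protons": 3},
        {"center": 4.115, "offsets": [-0.0205, -0.0068, 0.0068, 0.0205], "heights": [0.125, 0.375, 0.375, 0.125], "fwhm": 0.003, "protons": 1}
      ]
    },
    {
      "name": "betaine/TMAO",
      "synonyms": ["betaine", "TMAO", "trimethylamine N-oxide"],
      "resonances": [
        {"center": 3.265, "offsets": [0], "heights": [1], "fwhm": 0.003, "protons": 9},
        {"center": 3.90, "offsets": [0], "heights": [1], "fwhm": 0.003, "protons": 2}
      ]
    },
    {
      "name": "acetone",
      "synonyms": [],
      "resonances": [
        {"center": 2.225, "offsets": [0], "heights": [1], "fwhm": 0.003, "protons": 6}
      ]
    },
    {
      "name": "creatinine",
      "synonyms": [],
      "resonances": [
        {"center": 3.045, "offsets": [0], "heights": [1], "fwhm": 0.003, "protons": 3},
        {"center": 4.055, "offsets": [0], "heights": [1], "fwhm": 0.003, "protons": 2}
      ]
    },
    {
      "name": "creatine",
      "synonyms": [],
      "resonances": [
        {"center": 3.030, "offsets": [0], "heights": [1], "fwhm": 0.003, "protons": 3},
        {"center": 3.935, "offsets": [0], "heights": [1], "fwhm": 0.003, "protons": 2}
      ]
    },
    {
      "name": "formate",
      "synonyms": ["formic acid"],
      "resonances": [
        {"center": 8.455, "offsets": [0], "heights": [1], "fwhm": 0.003, "protons": 1}
      ]
    },
    {
      "name": "glycine",
      "synonyms": [],
      "resonances": [
        {"center": 3.565, "offsets": [0], "heights": [1], "fwhm": 0.003, "protons": 2}
      ]
    },
    {
      "name": "lysine",
      "synonyms": ["L-lysine"],
      "resonances": [
        {"center": 1.725, "offsets": [0], "heights": [1], "fwhm": 0.009, "protons": 2},
        {"center": 1.905, "offsets": [0], "heights": [1], "fwhm": 0.009, "protons": 2}
      ]
    },
    {
      "name": "acetate",
      "synonyms": ["acetic acid"],
      "resonances": [
        {"center": 1.925, "offsets": [0], "heights": [1], "fwhm": 0.003, "protons": 3}
      ]
    },
    {
      "name": "alanine",
      "synonyms": ["L-alanine"],
      "resonances": [
        {"center": 1.485, "offsets": [-0.0073, 0.0073], "heights": [0.5, 0.5], "fwhm": 0.003, "protons": 3}
      ]
    },
    {
      "name": "glutamate",
      "synonyms": ["L-glutamate", "glutamic acid"],
      "resonances": [
        {"center": 2.085, "offsets": [0], "heights": [1], "fwhm": 0.009, "protons": 2},
        {"center": 2.355, "offsets": [0], "heights": [1], "fwhm": 0.009, "protons": 2}
      ]
    },
    {
      "name": "3-hydroxybutyrate",
      "synonyms": ["3HB", "beta-hydroxybutyrate"],
      "resonances": [
        {"center": 1.205, "offsets": [-0.0063, 0.0063], "heights": [0.5, 0.5], "fwhm": 0.003, "protons": 3},
        {"center": 2.41, "offsets": [0], "heights": [1], "fwhm": 0.009, "protons": 1},
        {"center": 4.155, "offsets": [0], "heights": [1], "fwhm": 0.009, "protons": 1}
      ]
    },
    {
      "name": "methanol",
      "synonyms": [],
      "resonances": [
        {"center": 3.365, "offsets": [0], "heights": [1], "fwhm": 0.003, "protons": 3}
      ]
    },
    {
      "name": "myo-inositol",
      "synonyms": ["myoinositol"],
      "resonances": [
        {"center": 3.525, "offsets": [0], "heights": [1], "fwhm": 0.008, "protons": 2},
        {"center": 3.285, "offsets": [0], "heights": [1], "fwhm": 0.008, "protons": 1}
      ]
    },
    {
      "name": "trimethylamine",
      "synonyms": ["TMA"],
      "resonances": [
        {"center": 2.885, "offsets": [0], "heights": [1], "fwhm": 0.003, "protons": 9}
      ]
    },
    {
      "name": "valine",
      "synonyms": ["L-valine"],
      "resonances": [
        {"center": 0.985, "offsets": [-0.007, 0.007], "heights": [0.5, 0.5], "fwhm": 0.003, "protons": 3},
        {"center": 1.035, "offsets": [-0.007, 0.007], "heights": [0.5, 0.5], "fwhm": 0.003, "protons": 3}
      ]
    },
    {
      "name": "N-acetyl glycoprotein",
      "synonyms": ["NAC"],
      "resonances": [
        {"center": 2.045, "offsets": [0], "heights": [1], "fwhm": 0.010, "protons": 3}
      ]
    },
    {
      "name": "U1",
      "synonyms": [],
      "resonances": [
        {"center": 7.255, "offsets": [0], "heights": [1], "fwhm": 0.004, "protons": 1}
      ]
    },
    {
      "name": "U2",
      "synonyms": [],
      "resonances": [
        {"center": 7.685, "offsets": [0], "heights": [1], "fwhm": 0.004, "protons": 1}
      ]
    },
    {
      "name": "U3",
      "synonyms": [],
      "resonances": [
        {"center": 6.555, "offsets": [0], "heights": [1], "fwhm": 0.004, "protons": 1}
      ]
    },
    {
      "name": "U4",
      "synonyms": [],
      "resonances": [
        {"center": 7.055, "offsets": [0], "heights": [1], "fwhm": 0.004, "protons": 1}
      ]
    }
  ]
}
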