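{
 "air": {
  "density_g_cc": 0.001205,
  "table": "mu_air.tsv",
  "composition": {
   "C": 0.000124,
   "N": 0.755268,
   "O": 0.231781,
   "Ar": 0.012827
  }
 },
 "water": {
  "density_g_cc": 1.0,
  "table": "mu_water.tsv",
  "composition": {
   "H": 0.111894,
   "O": 0.888106
  }
 },
 "pmma": {
  "density_g_cc": 1.19,
  "table": "mu_pmma.tsv",
  "composition": {
   "H": 0.080538,
   "C": 0.599848,
   "O": 0.319614
  }
 },
 "adipose": {
  "density_g_cc": 0.95,
  "table": "mu_adipose.tsv",
  "composition": {
   "H": 0.114,
   "C": 0.598,
   "N": 0.007,
   "O": 0.278,
   "Na": 0.001,
   "S": 0.001,
   "Cl": 0.001
  }
 },
 "glandular": {
  "density_g_cc": 1.02,
  "table": "mu_glandular.tsv",
  "composition": {
   "H": 0.106,
   "C": 0.332,
   "N": 0.03,
   "O": 0.527,
   "Na": 0.001,
   "P": 0.001,
   "S": 0.002,
   "Cl": 0.001
  }
 },
 "muscle": {
  "density_g_cc": 1.05,
  "table": "mu_muscle.tsv",
  "composition": {
   "H": 0.102,
   "C": 0.143,
   "N": 0.034,
   "O": 0.71,
   "Na": 0.001,
   "P": 0.002,
   "S": 0.003,
   "Cl": 0.001,
   "K": 0.004
  }
 },
 "soft_tissue": {
  "density_g_cc": 1.06,
  "table": "mu_soft_tissue.tsv",
  "composition": {
   "H": 0.102,
   "C": 0.143,
   "N": 0.034,
   "O": 0.708,
   "Na": 0.002,
   "P": 0.003,
   "S": 0.003,
   "Cl": 0.002,
   "K": 0.003
  }
 },
 "skin": {
  "density_g_cc": 1.09,
  "table": "mu_skin.tsv",
  "composition": {
   "H": 0.1,
   "C": 0.204,
   "N": 0.042,
   "O": 0.645,
   "Na": 0.002,
   "P": 0.001,
   "S": 0.002,
   "Cl": 0.003,
   "K": 0.001
  }
 },
 "bone_cortical": {
  "density_g_cc": 1.92,
  "table": "mu_bone_cortical.tsv",
  "composition": {
   "H": 0.034,
   "C": 0.155,
   "N": 0.042,
   "O": 0.435,
   "Na": 0.001,
   "Mg": 0.002,
   "P": 0.103,
   "S": 0.003,
   "Ca": 0.225
  }
 },
 "aluminium": {
  "density_g_cc": 2.699,
  "table": "mu_aluminium.tsv",
  "composition": {
   "Al": 1.0
  }
 },
 "rhodium": {
  "density_g_cc": 12.41,
  "table": "mu_rhodium.tsv",
  "composition": {
   "Rh": 1.0
  }
 },
 "lead": {
  "density_g_cc": 11.35,
  "table": "mu_lead.tsv",
  "composition": {
   "Pb": 1.0
  }
 },
 "tungsten": {
  "density_g_cc": 19.3,
  "table": "mu_tungsten.tsv",
  "composition": {
   "W": 1.0
  }
 }
}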