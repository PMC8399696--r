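[
  {
    "name": "LENS1",
    "family": "superellipse",
    "params": {"a": 1, "b": 1.4, "p": 4, "q": 1.5},
    "group": "I",
    "parameterized": true,
    "kernel_kind": "rational",
    "provenance": "Lens exemplar: exponent ranges from the family definition (p > 2, 1 < q < 2); a, b chosen as representative for this package.",
    "exemplars": ["Cissus quadrangularis", "Cissus sterculiifolia", "Tetrastigma petraeum"]
  },
  {
    "name": "SE1",
    "family": "superellipse",
    "params": {"a": 1, "b": 1, "p": 4, "q": 4},
    "group": "II",
    "parameterized": true,
    "kernel_kind": "rational",
    "provenance": "Canonical superellipse exemplar: exponent ranges from the family definition (p, q > 2); a = b with p = q = 4 as the family's canonical representative.",
    "exemplars": ["Tetrastigma henryi", "Tetrastigma campylocarpum", "Tetrastigma caudatum"]
  },
  {
    "name": "VAM1",
    "family": "waterdrop",
    "params": {"a": 0.6, "b": 1, "c": 2},
    "group": "IV",
    "parameterized": true,
    "kernel_kind": "rational",
    "provenance": "Published water-drop model with printed parameters.",
    "exemplars": ["Vitis amurensis", "Vitis labrusca", "Vitis rupestris", "Cissus granulosa"]
  },
  {
    "name": "AGL1",
    "family": "waterdrop",
    "params": {"a": 0.3, "b": 1.1, "c": 1.6},
    "group": "IV",
    "parameterized": true,
    "kernel_kind": "rational",
    "provenance": "Published rounded water-drop model with printed parameters.",
    "exemplars": ["Ampelopsis glandulosa", "Tetrastigma triphyllum", "Cissus fuliginea"]
  },
  {
    "name": "AAR1",
    "family": "waterdrop",
    "params": {"a": 3, "b": 1, "c": 5},
    "group": "III",
    "parameterized": true,
    "kernel_kind": "rational",
    "provenance": "Published elongated water-drop model with printed parameters.",
    "exemplars": ["Ampelopsis arborea", "Cissus campestris", "Cissus willardii"]
  },
  {
    "name": "ACO1",
    "family": "heart",
    "params": {"a": 0.5, "b": 0.3333333333333333},
    "group": "V",
    "parameterized": true,
    "kernel_kind": "rational",
    "provenance": "Published heart-curve model with printed parameters.",
    "exemplars": ["Ampelopsis cordata", "Ampelopsis japonica", "Ampelopsis obtusata"]
  },
  {
    "name": "PHI1",
    "family": "heart_phi",
    "params": {"a": 0.3333333333333333, "b": 0.5},
    "group": "V",
    "parameterized": true,
    "kernel_kind": "rational",
    "provenance": "Published heart-curve model (broad beak kernel) with printed parameters.",
    "exemplars": ["Parthenocissus himalayana", "Parthenocissus heptaphylla", "Parthenocissus tricuspidata"]
  },
  {
    "name": "PPE1",
    "family": "heart_ppe",
    "params": {"a": 0.3333333333333333, "b": 0.3333333333333333},
    "group": "VIII",
    "parameterized": true,
    "kernel_kind": "rational",
    "provenance": "Published heart-curve model (flat basal entry) with printed parameters.",
    "exemplars": ["Pseudocayratia pengiana", "Pseudocayratia dichromocarpa", "Cayratia japonica"]
  },
  {
    "name": "ARO1",
    "family": "waterdrop",
    "params": {"a": 0.5, "b": 0.85, "c": 2},
    "group": "IX",
    "parameterized": false,
    "kernel_kind": "rational",
    "provenance": "Broadened heart-curve template; synthetic placeholder parameters, unverified - calibrate against the published model code.",
    "exemplars": ["Ampelocissus robinsonii"]
  },
  {
    "name": "AJA1",
    "family": "heart",
    "params": {"a": 0.35, "b": 0.25},
    "group": "IX",
    "parameterized": false,
    "kernel_kind": "rational",
    "provenance": "Squared heart-curve (SqHC) template; synthetic placeholder parameters, unverified - calibrate against the published model code.",
    "exemplars": ["Ampelocissus javalensis", "Ampelocissus cavicaulis", "Ampelocissus macrocirrha", "Ampelocissus ochracea"]
  },
  {
    "name": "AER1",
    "family": "waterdrop",
    "params": {"a": 0.4, "b": 0.9, "c": 2},
    "group": "IX",
    "parameterized": false,
    "kernel_kind": "rational",
    "provenance": "Broadened heart-curve template; synthetic placeholder parameters, unverified - calibrate against the published model code.",
    "exemplars": ["Ampelocissus erdvendbergiana"]
  },
  {
    "name": "AGR1",
    "family": "heart",
    "params": {"a": 0.3, "b": 0.3},
    "group": "IX",
    "parameterized": false,
    "kernel_kind": "rational",
    "provenance": "Broadened heart-curve template; synthetic placeholder parameters, unverified - calibrate against the published model code.",
    "exemplars": ["Ampelopsis grossedentata", "Ampelopsis denudata"]
  },
  {
    "name": "ADE1",
    "family": "heart",
    "params": {"a": 0.4, "b": 0.35},
    "group": "IX",
    "parameterized": false,
    "kernel_kind": "rational",
    "provenance": "Broadened heart-curve template; synthetic placeholder parameters, unverified - calibrate against the published model code.",
    "exemplars": ["Ampelopsis delavayana", "Ampelopsis cantoniensis"]
  },
  {
    "name": "AGR2",
    "family": "heart",
    "params": {"a": 0.6, "b": 0.25},
    "group": "IX",
    "parameterized": false,
    "kernel_kind": "rational",
    "provenance": "Squared heart-curve (SqHC) template; synthetic placeholder parameters, unverified - calibrate against the published model code.",
    "exemplars": ["Ampelocissus grantii", "Ampelocissus latifolia"]
  },
  {
    "name": "YAU1",
    "family": "waterdrop",
    "params": {"a": 1.5, "b": 0.9, "c": 4},
    "group": "VII",
    "parameterized": false,
    "kernel_kind": "rational",
    "provenance": "Pear-curve / elongated template; synthetic placeholder parameters, unverified - calibrate against the published model code.",
    "exemplars": ["Yua austro-orientalis", "Cissus trianae"]
  },
  {
    "name": "COL1",
    "family": "waterdrop",
    "params": {"a": 1.2, "b": 0.85, "c": 3},
    "group": "VII",
    "parameterized": false,
    "kernel_kind": "rational",
    "provenance": "Pear-curve / elongated template; synthetic placeholder parameters, unverified - calibrate against the published model code.",
    "exemplars": ["Cayratia oligocarpa"]
  },
  {
    "name": "VAE1",
    "family": "waterdrop",
    "params": {"a": 2, "b": 0.95, "c": 4.5},
    "group": "VII",
    "parameterized": false,
    "kernel_kind": "rational",
    "provenance": "Pear-curve / elongated template; synthetic placeholder parameters, unverified - calibrate against the published model code.",
    "exemplars": ["Yua chinensis", "Vitis aestivalis"]
  },
  {
    "name": "AME1",
    "family": "waterdrop",
    "params": {"a": 1.8, "b": 0.9, "c": 5},
    "group": "VII",
    "parameterized": false,
    "kernel_kind": "rational",
    "provenance": "Pear-curve / elongated template; synthetic placeholder parameters, unverified - calibrate against the published model code.",
    "exemplars": ["Ampelopsis megalophylla"]
  },
  {
    "name": "EHC1",
    "family": "heart",
    "params": {"a": 0.5, "b": 0.4},
    "group": "VI",
    "parameterized": false,
    "kernel_kind": "rational",
    "provenance": "Elongated heart-curve template; synthetic placeholder parameters, unverified - calibrate against the published model code.",
    "exemplars": ["Ampelocissus acapulcensis"]
  },
  {
    "name": "ESHC1",
    "family": "heart_phi",
    "params": {"a": 0.5, "b": 0.6},
    "group": "X",
    "parameterized": false,
    "kernel_kind": "rational",
    "provenance": "Elongated superellipse-heart curve (ESHC) template; synthetic placeholder parameters, unverified - calibrate against the published model code.",
    "exemplars": ["Rhoicissus rhomboidea", "Tetrastigma hemsleyanum"]
  }
]
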