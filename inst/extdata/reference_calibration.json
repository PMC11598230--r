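{
  "format": "admittr-calibration",
  "version": 1,
  "quadratic": [
    {
      "frequency_hz": 5000,
      "channel": "quadrature",
      "form": "quadratic",
      "alpha": [-0.169, 0.438, 0.016, 0.519, 0.025],
      "R": 0.998
    },
    {
      "frequency_hz": 5000,
      "channel": "in_phase",
      "form": "quadratic",
      "alpha": [0.684, 1.604, -0.120, 1.816, -0.117],
      "R": 0.985
    },
    {
      "frequency_hz": 10000,
      "channel": "quadrature",
      "form": "quadratic",
      "alpha": [-0.08, 0.236, 0.020, 0.309, 0.023],
      "R": 0.998
    },
    {
      "frequency_hz": 10000,
      "channel": "in_phase",
      "form": "quadratic",
      "alpha": [0.367, 1.275, -0.083, 1.503, -0.089],
      "R": 0.995
    }
  ],
  "linear": [
    {
      "frequency_hz": 5000,
      "channel": "quadrature",
      "form": "linear",
      "alpha": [-0.246, 0.502, 0, 0.62, 0],
      "R": 0.997
    },
    {
      "frequency_hz": 5000,
      "channel": "in_phase",
      "form": "linear",
      "alpha": [1.143, 1.110, 0, 1.333, 0],
      "R": 0.979
    },
    {
      "frequency_hz": 10000,
      "channel": "quadrature",
      "form": "linear",
      "alpha": [-0.163, 0.318, 0, 0.405, 0],
      "R": 0.996
    },
    {
      "frequency_hz": 10000,
      "channel": "in_phase",
      "form": "linear",
      "alpha": [0.7, 0.932, 0, 1.137, 0],
      "R": 0.990
    }
  ]
}
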