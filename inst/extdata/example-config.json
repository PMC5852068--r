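{
  "schema": "epifield-config-1",
  "params": {
    "I1": 3.1,
    "I2": 0.45,
    "tau0": 2857,
    "tau2": 10,
    "tau12": 100,
    "theta11": -1,
    "theta22": -0.5,
    "theta12": -1,
    "theta_het": -1,
    "a12": 3,
    "gamma11": 1,
    "gamma22": 1,
    "gamma12": 10,
    "u0": -1.8,
    "noise_sigma2": 0,
    "L": 18.8495559215388,
    "N": 128
  },
  "conn": {
    "n_fields": 1,
    "kernel": "laplacian",
    "het": []
  },
  "stimuli": [
    {
      "field": 1,
      "amplitude": 1,
      "width": 1.57,
      "center": null,
      "onset": 400,
      "duration": 10
    }
  ],
  "integration": {
    "duration": 2500,
    "dt": 0.025,
    "record_dt": 1
  },
  "analysis": {
    "window": 50,
    "band": [1, 10],
    "bandwidth": null
  },
  "seed": 1
}
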