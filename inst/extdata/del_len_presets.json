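{
  "version": "1.0",
  "model": "mixture of two shifted geometrics, support >= 3 bp",
  "bin_edges": [3, 10, 20, 50],
  "presets": {
    "WT.Cas9-CRU": {
      "p_short": 0.524805763864468,
      "p_long": 0.045142860800767,
      "lambda_long": 0.26374704038569,
      "shift_short": 5,
      "shift_long": 11,
      "target_bins": [0.57, 0.23, 0.15, 0.05],
      "printed": [true, true, true, true]
    },
    "parp1parp2.Cas9-CRU": {
      "p_short": 0.390386344571351,
      "p_long": 0.0493712366898613,
      "lambda_long": 0.530469011305111,
      "shift_short": 2,
      "shift_long": 7,
      "target_bins": [0.43, 0.25, 0.25, 0.07],
      "printed": [false, false, true, true]
    },
    "ku80.Cas9-CRU": {
      "p_short": 0.526173532570666,
      "p_long": 0.06673095045288,
      "lambda_long": 0.619897276762212,
      "shift_short": 6,
      "shift_long": 32,
      "target_bins": [0.2, 0.18, 0.4, 0.22],
      "printed": [false, false, true, true]
    },
    "ku80parp1parp2.Cas9-CRU": {
      "p_short": 0.214353577518919,
      "p_long": 0.0518287538544899,
      "lambda_long": 0.592286357745496,
      "shift_short": 4,
      "shift_long": 17,
      "target_bins": [0.21, 0.18, 0.49, 0.12],
      "printed": [false, false, true, true]
    },
    "WT.Cas9-PPO": {
      "p_short": 0.50748230459065,
      "p_long": 0.0599778765426258,
      "lambda_long": 0.349731010759227,
      "shift_short": 6,
      "shift_long": 31,
      "target_bins": [0.33, 0.32, 0.22, 0.13],
      "printed": [true, true, true, true]
    },
    "parp1parp2.Cas9-PPO": {
      "p_short": 0.189403432112576,
      "p_long": 0.0301892480898301,
      "lambda_long": 0.416967513124008,
      "shift_short": 4,
      "shift_long": 25,
      "target_bins": [0.27, 0.27, 0.24, 0.21],
      "printed": [true, true, true, true]
    },
    "ku80.Cas9-PPO": {
      "p_short": 0.150683296681901,
      "p_long": 0.0344996287039025,
      "lambda_long": 0.71602268032028,
      "shift_short": 4,
      "shift_long": 17,
      "target_bins": [0.11, 0.14, 0.5, 0.25],
      "printed": [false, false, false, false]
    },
    "ku80parp1parp2.Cas9-PPO": {
      "p_short": 0.153562208750983,
      "p_long": 0.0757130920841782,
      "lambda_long": 0.695093876120625,
      "shift_short": 4,
      "shift_long": 34,
      "target_bins": [0.12, 0.15, 0.48, 0.25],
      "printed": [false, false, false, false]
    }
  }
}
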