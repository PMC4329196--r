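{
  "schema_version": "1.0",
  "patients": {
    "A": {
      "params": {
        "vr": 13.3860377095553,
        "ie": 0.287892235672112,
        "rq": 0.553795223211758,
        "vo2": 316.122255604673,
        "collapsed_frac": 0.26271788163229,
        "top_sd": 7.59089428641782,
        "k_mean": 2.36398947474915,
        "pext_mean": 2.08350659783725,
        "raw_mean": 1.05302889743571,
        "cd": 0.793230009158769,
        "q_grad": 0.181158068452558,
        "tau_logmean": 3.10421468619089,
        "tau_logsd": 1.16981595793324,
        "d_close": 17.9911694101509
      },
      "seed": 101,
      "n": 100,
      "stage": "dynamic",
      "budget": 800,
      "checksum": 2074442525
    },
    "B": {
      "params": {
        "vr": 13.1808275200537,
        "ie": 0.261948411775798,
        "rq": 0.595928050032189,
        "vo2": 318.851954190262,
        "collapsed_frac": 0.274732449406973,
        "top_sd": 8.55608718326278,
        "k_mean": 2.37129315254839,
        "pext_mean": 2.04646417203533,
        "raw_mean": 0.980480620360018,
        "cd": 0.839772457597192,
        "q_grad": 0.283355305392049,
        "tau_logmean": 3.10421468619089,
        "tau_logsd": 1.16981595793324,
        "d_close": 17.9911694101509
      },
      "seed": 102,
      "n": 100,
      "stage": "dynamic",
      "budget": 800,
      "checksum": 1129978834
    },
    "C": {
      "params": {
        "vr": 16.6083441827939,
        "ie": 0.408482053552029,
        "rq": 1.0015289025629,
        "vo2": 162.126317250799,
        "collapsed_frac": 0.119339439494626,
        "top_sd": 7.77330304412388,
        "k_mean": 3.641109814429,
        "pext_mean": 1.99736815547544,
        "raw_mean": 1.02834145937945,
        "cd": 0.862251529205481,
        "q_grad": 0.381767825985952,
        "tau_logmean": 2.80598783987128,
        "tau_logsd": 1.33611111111111,
        "d_close": 17.9583333333333
      },
      "seed": 103,
      "n": 100,
      "stage": "dynamic",
      "budget": 800,
      "checksum": 936698407
    },
    "D": {
      "params": {
        "vr": 17.8539070793717,
        "ie": 0.401070680699017,
        "rq": 0.731409547403858,
        "vo2": 250.902357945153,
        "collapsed_frac": 0.198389014246199,
        "top_sd": 8.22428937756629,
        "k_mean": 3.15971667794058,
        "pext_mean": 2.20001376349368,
        "raw_mean": 0.989551944451973,
        "cd": 0.822323088163581,
        "q_grad": 0.500268669570781,
        "tau_logmean": 3.10421468619089,
        "tau_logsd": 1.16981595793324,
        "d_close": 17.9911694101509
      },
      "seed": 104,
      "n": 100,
      "stage": "dynamic",
      "budget": 800,
      "checksum": 1809281605
    },
    "E": {
      "params": {
        "vr": 17.5570262351638,
        "ie": 0.447348037860505,
        "rq": 0.579915356336446,
        "vo2": 205.303449281609,
        "collapsed_frac": 0.208813848326148,
        "top_sd": 7.94924361588588,
        "k_mean": 2.97421274184969,
        "pext_mean": 1.98076552122493,
        "raw_mean": 1.08374539641409,
        "cd": 0.913079195631002,
        "q_grad": 1.00087229953431,
        "tau_logmean": 3.10421468619089,
        "tau_logsd": 1.16981595793324,
        "d_close": 17.9911694101509
      },
      "seed": 105,
      "n": 100,
      "stage": "dynamic",
      "budget": 800,
      "checksum": 1145979561
    }
  }
}
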