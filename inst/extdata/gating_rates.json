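{
  "format_version": 1,
  "description": "Voltage-dependent opening (alpha) and closing (beta) rate coefficients for the Na+ activation (m) and inactivation (h) gates, the Kv1 activation gate (n1) and the Kv3 activation gate (n3) of the fast-spiking interneuron model. Rates in ms^-1, voltages in mV. Templates: linoid = C*(V-V_h)/(exp((V-V_h)/s)-1) (value C*s at V = V_h), exponential = C*exp((V-V_h)/s), sigmoid = C/(1+exp(-(V-V_h)/s)), constant = C.",
  "source": "Transcribed from the fast-spiking neocortical interneuron model of Erisir, Lau, Rudy and Leonard (1999) J Neurophysiol 82:2476-2489, with the rate-function corrections used by Mancilla, Lewis, Pinto, Rinzel and Connors (2007) J Neurosci 27:2058-2073.",
  "gates": {
    "m": {
      "alpha": {"template": "linoid", "C": -40.0, "V_h": 75.5, "s": -13.5},
      "beta": {"template": "exponential", "C": 1.2262, "V_h": 0.0, "s": -42.248}
    },
    "h": {
      "alpha": {"template": "exponential", "C": 0.0035, "V_h": 0.0, "s": -24.186},
      "beta": {"template": "linoid", "C": -0.017, "V_h": -51.25, "s": -5.2}
    },
    "n1": {
      "alpha": {"template": "linoid", "C": -0.014, "V_h": -44.0, "s": -2.3},
      "beta": {"template": "exponential", "C": 0.0043, "V_h": -44.0, "s": -34.0}
    },
    "n3": {
      "alpha": {"template": "linoid", "C": -1.0, "V_h": 95.0, "s": -11.8},
      "beta": {"template": "exponential", "C": 0.025, "V_h": 0.0, "s": -22.222}
    }
  }
}
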