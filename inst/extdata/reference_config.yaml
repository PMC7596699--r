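# Reference configuration: the default parameter set written out in full.
model:
  C: 20
  gL: 2.8
  gNaP: 5
  EL: -65
  ENa: 50
  Eex: -10
  Einh: -90
  VmNaP: -40
  kmNaP: -6
  VhNaP: -50
  khNaP: 10
  tauNaP: 1500
  VtauNaP: -100
  ktauNaP: 40
  Vmin: -50
  Vmax: 0
  b12: 0.4
  b21: 0.4
  b31: 0.5
  b42: 0.5
  b13: 1
  b24: 1
  b41: 0.2
  b32: 0.2
  DE0: 1.4
drives:
  dF_left: 0.5
  dF_right: 0.5
  coupled: true
solver:
  method: lsoda
  duration: 40000
  transient: 10000
seed: 0
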