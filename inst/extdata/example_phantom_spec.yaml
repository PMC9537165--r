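shape:
- 64
- 64
- 64
spacing:
- 4.0
- 4.0
- 4.0
background: 1.0
organs:
- label: body
  cx: 126.0
  cy: 126.0
  cz: 126.0
  rx: 100.8
  ry: 85.68
  rz: 115.92
  mult: 100.0
  mu: 0.0096
- label: lung
  cx: 70.56
  cy: 113.4
  cz: 171.36
  rx: 32.76
  ry: 30.24
  rz: 40.32
  mult: 30.0
  mu: 0.003
- label: lung
  cx: 181.44
  cy: 113.4
  cz: 171.36
  rx: 32.76
  ry: 30.24
  rz: 40.32
  mult: 30.0
  mu: 0.003
- label: liver
  cx: 166.32
  cy: 131.04
  cz: 120.96
  rx: 42.84
  ry: 32.76
  rz: 27.72
  mult: 200.0
  mu: 0.0098
- label: heart
  cx: 105.84
  cy: 105.84
  cz: 166.32
  rx: 25.2
  ry: 22.68
  rz: 22.68
  mult: 250.0
  mu: 0.0096
- label: kidney
  cx: 80.64
  cy: 156.24
  cz: 80.64
  rx: 17.64
  ry: 15.12
  rz: 22.68
  mult: 220.0
  mu: 0.0096
- label: kidney
  cx: 171.36
  cy: 156.24
  cz: 80.64
  rx: 17.64
  ry: 15.12
  rz: 22.68
  mult: 220.0
  mu: 0.0096
- label: spine
  cx: 126.0
  cy: 191.52
  cz: 126.0
  rx: 12.6
  ry: 12.6
  rz: 110.88
  mult: 50.0
  mu: 0.017
lesions:
- label: lesion1
  cx: 161.28
  cy: 120.96
  cz: 115.92
  r: 11.34
  mult: 500.0
- label: lesion2
  cx: 75.6
  cy: 126.0
  cz: 75.6
  r: 8.82
  mult: 600.0
tracerProfile: fdg
psfFwhm: 5.0
noiseScale: 4.0
scatterFraction: 0.25
scatterFwhm: 40.0
nAngles: 8
seed: 1
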