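species:
- name: glc_ext
  c0: 5.0
  external: yes
- name: o2_ext
  c0: 20.0
  external: yes
- name: lac_ext
  c0: 1.5
  external: yes
- name: g6p
  c0: 0.29999999999999999
  external: no
- name: p6g
  c0: 0.02
  external: no
- name: f16bp
  c0: 0.29999999999999999
  external: no
- name: pyr
  c0: 0.10000000000000001
  external: no
- name: lac
  c0: 1.5
  external: no
- name: accoa
  c0: 0.05
  external: no
reactions:
- name: hk
  J0: 3.29999999999999982
  cE: 1.0
  stoich:
    glc_ext: -1.0
    g6p: 1.0
  elasticities:
    substrate:
      glc_ext: 0.5
    product:
      g6p: -0.20000000000000001
- name: ppp_ox
  J0: 0.66000000000000003
  cE: 1.0
  stoich:
    g6p: -1.0
    p6g: 1.0
  elasticities:
    substrate:
      g6p: 1.0
    product:
      p6g: -0.20000000000000001
- name: ppp_return
  J0: 0.66000000000000003
  cE: 1.0
  stoich:
    p6g: -1.0
    f16bp: 1.0
  elasticities:
    substrate:
      p6g: 1.0
- name: pfk
  J0: 2.64000000000000012
  cE: 1.0
  stoich:
    g6p: -1.0
    f16bp: 1.0
  elasticities:
    substrate:
      g6p: 0.90000000000000002
    product:
      f16bp: -0.20000000000000001
- name: pk
  J0: 3.29999999999999982
  cE: 1.0
  stoich:
    f16bp: -1.0
    pyr: 2.0
  elasticities:
    substrate:
      f16bp: 0.80000000000000004
    product:
      pyr: -0.20000000000000001
- name: ldh
  J0: 4.0
  cE: 1.0
  stoich:
    pyr: -1.0
    lac: 1.0
  elasticities:
    substrate:
      pyr: 1.19999999999999996
    product:
      lac: -0.20000000000000001
- name: lac_export
  J0: 4.0
  cE: 1.0
  stoich:
    lac: -1.0
    lac_ext: 1.0
  elasticities:
    substrate:
      lac: 1.0
    product:
      lac_ext: -0.10000000000000001
- name: pdh
  J0: 2.60000000000000009
  cE: 1.0
  stoich:
    pyr: -1.0
    accoa: 1.0
  elasticities:
    substrate:
      pyr: 1.0
    activator:
      o2_ext: 0.20000000000000001
    product:
      accoa: -0.20000000000000001
- name: respiration
  J0: 2.60000000000000009
  cE: 1.0
  stoich:
    accoa: -1.0
    o2_ext: -6.0
  elasticities:
    substrate:
      accoa: 1.0
      o2_ext: 0.5
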