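variables:
- name: age
  levels:
  - 16-44
  - 45+
  reference: 16-44
- name: sex
  levels:
  - female
  - male
  reference: female
- name: ethnicity
  levels:
  - non-white
  - white
  reference: non-white
- name: english
  levels:
  - 'no'
  - 'yes'
  reference: 'no'
- name: ukborn
  levels:
  - 'no'
  - 'yes'
  reference: 'no'
- name: qualification
  levels:
  - level1_or_below
  - level2_plus
  reference: level1_or_below
- name: income
  levels:
  - lt10k
  - ge10k
  - other
  reference: lt10k
- name: job
  levels:
  - higher
  - intermediate
  - lower
  reference: higher
- name: working
  levels:
  - 'no'
  - 'yes'
  reference: 'no'
- name: ownhome
  levels:
  - 'no'
  - 'yes'
  reference: 'no'
- name: imd
  levels:
  - q1
  - q2
  - q3
  - q4
  - q5
  reference: q1

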