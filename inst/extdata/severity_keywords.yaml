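# Dual-axis clinical severity quantification: keyword -> 1-5 severity level.
# Level 5 = most severe / psychotic features ... level 1 = subclinical.
# Matching is case-insensitive, fixed phrases; the highest matched level wins.
severity_keywords:
  5:
    - severe depression with psychotic symptoms
    - mood disorder
    - phantosmia
    - suicidal ideation
    - panic attacks
  4:
    - depressive episode
    - mixed anxiety-depressive disorder
    - severe anxiety
  3:
    - depressive state
    - anxious depressive state
    - emotional and behavioral disorders
    - adjustment disorder
  2:
    - sleep disorder
    - emotional disorders in children
    - mild anxiety
  1:
    - psychological consultation
    - no significant abnormality
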