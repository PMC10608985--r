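# End-to-end analysis configuration for the packaged thiosemicarbazide
# retention study (18 compounds, five chromatographic systems).
inputs:
  retention: null                  # raw isocratic measurements (none shipped)
  retention_fits: retention_fits.csv
  protein_logk: protein_logk.csv
  references: null                 # calibration drugs: user data; fall back to curves below
  insilico: insilico_logp.csv
  extra_descriptors: qsar_logK.csv   # QSAR-predicted plasma-binding log K
calibration:
  HSA: {intercept: 0.2513, slope: 1.0525}
  AGP: {intercept: 0.1733, slope: 0.8902}
regressions:
  - {name: logkw_IAM_vs_C18,   response: logkw_IAM,  predictor: logkw_C18,  exclude: [16]}
  - {name: logkw_Chol_vs_C18,  response: logkw_Chol, predictor: logkw_C18,  exclude: [16]}
  - {name: logkw_Chol_vs_IAM,  response: logkw_Chol, predictor: logkw_IAM,  exclude: []}
  - {name: logK_HSA_vs_IAM,    response: logK_HSA,   predictor: logkw_IAM,  exclude: []}
  - {name: logK_AGP_vs_IAM,    response: logK_AGP,   predictor: logkw_IAM,  exclude: []}
  - {name: logK_AGP_vs_IRFMN,  response: logK_AGP,   predictor: logK_IRFMN, exclude: [2, 9]}
correlations:
  rows: [logP, ClogP, SlogP, SlogD, MlogP, AlogP, logP_MK]
  cols: [logkw_C18, logkw_IAM, logkw_Chol, logK_HSA, logK_AGP]
  exclude:
    logP|logkw_C18: [4, 16]
    logP|logkw_IAM: [4, 16]
    logP|logkw_Chol: [4, 16]
    logP|logK_HSA: [4, 16]
    ClogP|logkw_C18: [16]
    ClogP|logkw_IAM: [16]
    ClogP|logkw_Chol: [4, 16]
    ClogP|logK_HSA: [7, 16]
    ClogP|logK_AGP: [13]
    SlogP|logkw_C18: [16]
    SlogP|logkw_IAM: [18]
    SlogP|logkw_Chol: [4, 16]
    SlogP|logK_HSA: [7]
    SlogP|logK_AGP: [13]
    SlogD|logkw_C18: [16]
    SlogD|logkw_Chol: [4, 16]
    SlogD|logK_HSA: [7]
    SlogD|logK_AGP: [13]
    MlogP|logkw_C18: [16]
    MlogP|logkw_IAM: [16]
    MlogP|logkw_Chol: [4, 16]
    MlogP|logK_HSA: [7]
    MlogP|logK_AGP: [13]
    AlogP|logkw_C18: [16]
    AlogP|logkw_Chol: [8, 16]
    AlogP|logK_AGP: [13]
    logP_MK|logkw_C18: [4, 16]
    logP_MK|logkw_Chol: [4, 16]
    logP_MK|logK_HSA: [16]
    logP_MK|logK_AGP: [13]
summary_columns: [logkw_C18, logkw_IAM, logkw_Chol, logk_HSA, logk_AGP,
                  minus_S_C18, minus_S_IAM, minus_S_Chol]
pca:
  columns: [logkw_C18, logkw_IAM, logkw_Chol, logk_HSA, logk_AGP]
  n_components: 2
rounding: {coef: 4, ppb: 1, r: 2, summary: 3}
seed: 1
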