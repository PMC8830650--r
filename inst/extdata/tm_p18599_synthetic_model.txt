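# Synthetic surrogate parameters for the 3-state transmembrane example.
# The emission rows derive from background amino-acid frequencies:
# M reweighted by exp(0.7 * Kyte-Doolittle hydropathy), I with K/R x1.8,
# O with polar residues x1.4; transitions satisfy a(I->O)=a(O->I)=0 and
# near-1 self-transitions for I and M. NOT trained parameters.
alphabet: protein
states: I M O
prior: 0.59999999999999998 0.10000000000000001 0.29999999999999999
transitions:
I 0.97999999999999998 0.02 0
M 0.025000000000000001 0.94999999999999996 0.025000000000000001
O 0 0.029999999999999999 0.96999999999999997
emissions:
I 0.076049111233278371 0.012827560930914424 0.050393989371449517 0.0613890415979476 0.035733919736118752 0.065054059006780282 0.02107385010078798 0.054059006780282207 0.095656954370533273 0.088876672164192788 0.021990104452996154 0.037566428440535093 0.043063954553784131 0.035733919736118752 0.090709180868609129 0.060472787245739422 0.049477735019241346 0.063221550302363941 0.010078797874289903 0.026571376214037021
M 0.058605415242127104 0.016135855159966499 0.00095058250420327586 0.0011579823233021725 0.055453683506437736 0.010747426943526204 0.00049040716238417013 0.27575807423376358 0.00075762215440305567 0.27774334651613053 0.018174878259175478 0.00070861604858789653 0.0030714018821318056 0.00067404941207141369 0.00047204530162858245 0.0075507072684847945 0.0066257961706682337 0.26141076943109598 0.0011733721321756907 0.002337968347735741
O 0.072717715086735593 0.012265638689328895 0.067461012791308922 0.082179779218503585 0.034168564920273349 0.062204310495882244 0.020150692132468898 0.051690905905028908 0.050814788855791139 0.084983353776064488 0.021026809181706678 0.05028911862624847 0.041177501314175573 0.047835990888382689 0.048186437708077803 0.080953215349570701 0.066234448922376038 0.060452076397406698 0.0096372875416155593 0.035570352199053794
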