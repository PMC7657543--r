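grammar G6X
version 1
tS 7.839425587e-01 2.160574413e-01
tL 1.566011236e-01 8.433988764e-01
tF 7.896713615e-01 2.093896714e-01 9.389671362e-04
e_single 3.546511628e-01 1.719269103e-01 2.284053156e-01 2.450166113e-01
e_pair 4.201680672e-03 4.201680672e-03 4.201680672e-03 1.890756303e-01 4.201680672e-03 4.201680672e-03 2.394957983e-01 4.201680672e-03 4.201680672e-03 2.310924370e-01 4.201680672e-03 1.134453782e-01 1.470588235e-01 4.201680672e-03 3.781512605e-02 4.201680672e-03
e_stack_AA 4.201680672e-03 4.201680672e-03 4.201680672e-03 1.890756303e-01 4.201680672e-03 4.201680672e-03 2.394957983e-01 4.201680672e-03 4.201680672e-03 2.310924370e-01 4.201680672e-03 1.134453782e-01 1.470588235e-01 4.201680672e-03 3.781512605e-02 4.201680672e-03
e_stack_CA 4.201680672e-03 4.201680672e-03 4.201680672e-03 1.890756303e-01 4.201680672e-03 4.201680672e-03 2.394957983e-01 4.201680672e-03 4.201680672e-03 2.310924370e-01 4.201680672e-03 1.134453782e-01 1.470588235e-01 4.201680672e-03 3.781512605e-02 4.201680672e-03
e_stack_GA 4.201680672e-03 4.201680672e-03 4.201680672e-03 1.890756303e-01 4.201680672e-03 4.201680672e-03 2.394957983e-01 4.201680672e-03 4.201680672e-03 2.310924370e-01 4.201680672e-03 1.134453782e-01 1.470588235e-01 4.201680672e-03 3.781512605e-02 4.201680672e-03
e_stack_UA 6.888001102e-05 6.888001102e-05 6.888001102e-05 1.998209120e-01 6.888001102e-05 6.888001102e-05 3.809753410e-01 6.888001102e-05 6.888001102e-05 1.677228268e-01 6.888001102e-05 5.104008817e-02 1.499517840e-01 6.888001102e-05 4.980024797e-02 6.888001102e-05
e_stack_AC 4.201680672e-03 4.201680672e-03 4.201680672e-03 1.890756303e-01 4.201680672e-03 4.201680672e-03 2.394957983e-01 4.201680672e-03 4.201680672e-03 2.310924370e-01 4.201680672e-03 1.134453782e-01 1.470588235e-01 4.201680672e-03 3.781512605e-02 4.201680672e-03
e_stack_CC 4.201680672e-03 4.201680672e-03 4.201680672e-03 1.890756303e-01 4.201680672e-03 4.201680672e-03 2.394957983e-01 4.201680672e-03 4.201680672e-03 2.310924370e-01 4.201680672e-03 1.134453782e-01 1.470588235e-01 4.201680672e-03 3.781512605e-02 4.201680672e-03
e_stack_GC 3.560746332e-05 3.560746332e-05 3.560746332e-05 1.117718274e-01 3.560746332e-05 3.560746332e-05 3.325381000e-01 3.560746332e-05 3.560746332e-05 2.731448512e-01 3.560746332e-05 2.638513032e-02 1.792123629e-01 3.560746332e-05 7.659165361e-02 3.560746332e-05
e_stack_UC 4.201680672e-03 4.201680672e-03 4.201680672e-03 1.890756303e-01 4.201680672e-03 4.201680672e-03 2.394957983e-01 4.201680672e-03 4.201680672e-03 2.310924370e-01 4.201680672e-03 1.134453782e-01 1.470588235e-01 4.201680672e-03 3.781512605e-02 4.201680672e-03
e_stack_AG 4.201680672e-03 4.201680672e-03 4.201680672e-03 1.890756303e-01 4.201680672e-03 4.201680672e-03 2.394957983e-01 4.201680672e-03 4.201680672e-03 2.310924370e-01 4.201680672e-03 1.134453782e-01 1.470588235e-01 4.201680672e-03 3.781512605e-02 4.201680672e-03
e_stack_CG 3.591180062e-05 3.591180062e-05 3.591180062e-05 1.554621849e-01 3.591180062e-05 3.591180062e-05 2.926452632e-01 3.591180062e-05 3.591180062e-05 2.498383969e-01 3.591180062e-05 7.789269554e-02 1.465560583e-01 3.591180062e-05 7.724628313e-02 3.591180062e-05
e_stack_GG 4.201680672e-03 4.201680672e-03 4.201680672e-03 1.890756303e-01 4.201680672e-03 4.201680672e-03 2.394957983e-01 4.201680672e-03 4.201680672e-03 2.310924370e-01 4.201680672e-03 1.134453782e-01 1.470588235e-01 4.201680672e-03 3.781512605e-02 4.201680672e-03
e_stack_UG 1.355380862e-04 1.355380862e-04 1.355380862e-04 1.028734074e-01 1.355380862e-04 1.355380862e-04 1.690159935e-01 1.355380862e-04 1.355380862e-04 4.268094335e-01 1.355380862e-04 6.817565736e-02 1.660341556e-01 1.355380862e-04 6.573597181e-02 1.355380862e-04
e_stack_AU 5.835667600e-05 5.835667600e-05 5.835667600e-05 1.692927171e-01 5.835667600e-05 5.835667600e-05 2.672152194e-01 5.835667600e-05 5.835667600e-05 3.226540616e-01 5.835667600e-05 5.713118581e-02 1.131535948e-01 5.835667600e-05 6.996965453e-02 5.835667600e-05
e_stack_CU 4.201680672e-03 4.201680672e-03 4.201680672e-03 1.890756303e-01 4.201680672e-03 4.201680672e-03 2.394957983e-01 4.201680672e-03 4.201680672e-03 2.310924370e-01 4.201680672e-03 1.134453782e-01 1.470588235e-01 4.201680672e-03 3.781512605e-02 4.201680672e-03
e_stack_GU 1.556178027e-04 1.556178027e-04 1.556178027e-04 8.107687519e-02 1.556178027e-04 1.556178027e-04 3.422035481e-01 1.556178027e-04 1.556178027e-04 3.048552754e-01 1.556178027e-04 1.153127918e-01 1.165577342e-01 1.556178027e-04 3.843759726e-02 1.556178027e-04
e_stack_UU 4.201680672e-03 4.201680672e-03 4.201680672e-03 1.890756303e-01 4.201680672e-03 4.201680672e-03 2.394957983e-01 4.201680672e-03 4.201680672e-03 2.310924370e-01 4.201680672e-03 1.134453782e-01 1.470588235e-01 4.201680672e-03 3.781512605e-02 4.201680672e-03
e_pair_parallel 4.201680672e-03 4.201680672e-03 4.201680672e-03 1.890756303e-01 4.201680672e-03 4.201680672e-03 2.394957983e-01 4.201680672e-03 4.201680672e-03 2.310924370e-01 4.201680672e-03 1.134453782e-01 1.470588235e-01 4.201680672e-03 3.781512605e-02 4.201680672e-03
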