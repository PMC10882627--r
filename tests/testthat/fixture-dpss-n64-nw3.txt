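# DPSS tapers, n=64 NW=3 K=5, computed with scipy.signal.windows.dpss
# last line: concentration ratios
3.564442102337369e-04 7.911887850688527e-04 1.468275836362010e-03 2.459278530838178e-03 3.843445917891106e-03 5.705862477870446e-03 8.135016082496616e-03 1.121981547727676e-02 1.504613243095818e-02 1.969297685051002e-02 2.522844345267602e-02 3.170559406605052e-02 3.915845851320466e-02 4.759834776152256e-02 5.701067448039689e-02 6.735246761187445e-02 7.855074889118041e-02 9.050191084630459e-02 1.030721986321149e-01 1.160993536194617e-01 1.293954269389045e-01 1.427507185225576e-01 1.559387442010052e-01 1.687220828149812e-01 1.808589097775964e-01 1.921099855682455e-01 2.022458394163851e-01 2.110538716418130e-01 2.183450938896991e-01 2.239602353230299e-01 2.277749645213884e-01 2.297040105117530e-01 2.297040105117532e-01 2.277749645213887e-01 2.239602353230303e-01 2.183450938896996e-01 2.110538716418133e-01 2.022458394163855e-01 1.921099855682459e-01 1.808589097775967e-01 1.687220828149815e-01 1.559387442010055e-01 1.427507185225579e-01 1.293954269389048e-01 1.160993536194620e-01 1.030721986321152e-01 9.050191084630481e-02 7.855074889118059e-02 6.735246761187458e-02 5.701067448039699e-02 4.759834776152262e-02 3.915845851320470e-02 3.170559406605054e-02 2.522844345267604e-02 1.969297685051002e-02 1.504613243095818e-02 1.121981547727675e-02 8.135016082496614e-03 5.705862477870445e-03 3.843445917891106e-03 2.459278530838178e-03 1.468275836362010e-03 7.911887850688527e-04 3.564442102337369e-04
2.507242465803633e-03 4.862418633006515e-03 8.170215199136834e-03 1.258459272933677e-02 1.824082140728403e-02 2.524502150082670e-02 3.366378493218215e-02 4.351447586966223e-02 5.475682702047175e-02 6.728643144737721e-02 8.093067580344815e-02 9.544757068288331e-02 1.105278104482945e-01 1.258002437792497e-01 1.408407646598590e-01 1.551844505797909e-01 1.683405904923376e-01 1.798100702314574e-01 1.891044282180992e-01 1.957657692110568e-01 1.993866370183006e-01 1.996289049684083e-01 1.962407496252538e-01 1.890708300594791e-01 1.780789004271707e-01 1.633422332409928e-01 1.450574174721590e-01 1.235373101090376e-01 9.920315084705222e-02 7.257208486732497e-02 4.424056541030705e-02 1.486431360761743e-02 -1.486431360761802e-02 -4.424056541030762e-02 -7.257208486732550e-02 -9.920315084705268e-02 -1.235373101090379e-01 -1.450574174721593e-01 -1.633422332409929e-01 -1.780789004271707e-01 -1.890708300594789e-01 -1.962407496252535e-01 -1.996289049684080e-01 -1.993866370183004e-01 -1.957657692110565e-01 -1.891044282180990e-01 -1.798100702314572e-01 -1.683405904923375e-01 -1.551844505797908e-01 -1.408407646598589e-01 -1.258002437792495e-01 -1.105278104482943e-01 -9.544757068288313e-02 -8.093067580344798e-02 -6.728643144737706e-02 -5.475682702047160e-02 -4.351447586966210e-02 -3.366378493218204e-02 -2.524502150082662e-02 -1.824082140728397e-02 -1.258459272933673e-02 -8.170215199136806e-03 -4.862418633006498e-03 -2.507242465803625e-03
1.183922072218796e-02 1.986776364001525e-02 2.993640846851197e-02 4.202894515445504e-02 5.601642306764943e-02 7.164915447462705e-02 8.855507356763249e-02 1.062451399066254e-01 1.241260828539277e-01 1.415203463167649e-01 1.576926371022032e-01 1.718820341999767e-01 1.833382097900060e-01 1.913599738897356e-01 1.953341082526470e-01 1.947723213289166e-01 1.893441482050321e-01 1.789037432192072e-01 1.635087659059966e-01 1.434299322005879e-01 1.191502736806684e-01 9.135369240033261e-02 6.090298652956392e-02 2.880811797987207e-02 -3.813938480124510e-03 -3.578591948169634e-02 -6.592131447805973e-02 -9.307717822514194e-02 -1.162060190459553e-01 -1.344040703287349e-01 -1.469534092816110e-01 -1.533556899040220e-01 -1.533556899040220e-01 -1.469534092816111e-01 -1.344040703287352e-01 -1.162060190459556e-01 -9.307717822514235e-02 -6.592131447806018e-02 -3.578591948169684e-02 -3.813938480125039e-03 2.880811797987153e-02 6.090298652956340e-02 9.135369240033213e-02 1.191502736806679e-01 1.434299322005876e-01 1.635087659059963e-01 1.789037432192069e-01 1.893441482050318e-01 1.947723213289163e-01 1.953341082526468e-01 1.913599738897353e-01 1.833382097900058e-01 1.718820341999764e-01 1.576926371022030e-01 1.415203463167646e-01 1.241260828539275e-01 1.062451399066253e-01 8.855507356763237e-02 7.164915447462696e-02 5.601642306764935e-02 4.202894515445498e-02 2.993640846851192e-02 1.986776364001522e-02 1.183922072218794e-02
4.241528286250638e-02 6.104540201366166e-02 8.150486939958916e-02 1.030130993614261e-01 1.246367866697706e-01 1.453332017421591e-01 1.640038945411074e-01 1.795559518941842e-01 1.909672841145920e-01 1.973519566224258e-01 1.980213714489296e-01 1.925371666893889e-01 1.807520454977043e-01 1.628353571198532e-01 1.392810988088029e-01 1.108970400501958e-01 7.877482586671419e-02 4.424212033889844e-02 8.799025804848475e-03 -2.595792159290886e-02 -5.841999685924260e-02 -8.705395161296595e-02 -1.104879366389267e-01 -1.275904969974843e-01 -1.375377642953670e-01 -1.398645960137592e-01 -1.344963178447976e-01 -1.217588572016861e-01 -1.023663440957748e-01 -7.738661792313141e-02 -4.818642813426929e-02 -1.635936613063985e-02 1.635936613064004e-02 4.818642813426947e-02 7.738661792313153e-02 1.023663440957750e-01 1.217588572016862e-01 1.344963178447977e-01 1.398645960137593e-01 1.375377642953671e-01 1.275904969974844e-01 1.104879366389269e-01 8.705395161296611e-02 5.841999685924276e-02 2.595792159290901e-02 -8.799025804848327e-03 -4.424212033889832e-02 -7.877482586671410e-02 -1.108970400501957e-01 -1.392810988088029e-01 -1.628353571198533e-01 -1.807520454977045e-01 -1.925371666893892e-01 -1.980213714489299e-01 -1.973519566224261e-01 -1.909672841145922e-01 -1.795559518941844e-01 -1.640038945411076e-01 -1.453332017421592e-01 -1.246367866697707e-01 -1.030130993614262e-01 -8.150486939958924e-02 -6.104540201366172e-02 -4.241528286250642e-02
1.160563702280526e-01 1.425246746243581e-01 1.663497402168561e-01 1.860036501509067e-01 2.001113279618131e-01 2.075484680701807e-01 2.075271492299691e-01 1.996626949444664e-01 1.840164382953521e-01 1.611105591109944e-01 1.319129911176081e-01 9.779242207820238e-02 6.044549011508041e-02 2.180026640135810e-02 -1.609813632194012e-02 -5.121260873460554e-02 -8.164161597263365e-02 -1.057408090722254e-01 -1.222304176808451e-01 -1.302809707629068e-01 -1.295712303510293e-01 -1.203140084357077e-01 -1.032476499692845e-01 -7.959326183138166e-02 -5.098008971521002e-02 -1.934362987786096e-02 1.319704379426837e-02 4.447479008148312e-02 7.241386664060044e-02 9.516413854467014e-02 1.112211125854516e-01 1.195237898469893e-01 1.195237898469893e-01 1.112211125854516e-01 9.516413854467019e-02 7.241386664060052e-02 4.447479008148322e-02 1.319704379426848e-02 -1.934362987786086e-02 -5.098008971520993e-02 -7.959326183138157e-02 -1.032476499692844e-01 -1.203140084357077e-01 -1.295712303510293e-01 -1.302809707629068e-01 -1.222304176808451e-01 -1.057408090722254e-01 -8.164161597263368e-02 -5.121260873460561e-02 -1.609813632194022e-02 2.180026640135797e-02 6.044549011508026e-02 9.779242207820220e-02 1.319129911176080e-01 1.611105591109943e-01 1.840164382953520e-01 1.996626949444662e-01 2.075271492299689e-01 2.075484680701805e-01 2.001113279618128e-01 1.860036501509066e-01 1.663497402168560e-01 1.425246746243581e-01 1.160563702280525e-01
9.999998730411327e-01 9.999911515902709e-01 9.997233692255520e-01 9.950049123408422e-01 9.465841836456270e-01
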