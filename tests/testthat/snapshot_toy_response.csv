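"frequency_Hz","x_mm","Re_u_m","Im_u_m","abs_u_m","normalized_abs"
1000,0,-4.64615184779003e-09,3.55018622239581e-09,5.84726852525277e-09,0.584726852525277
1000,0.04,-5.12442176609185e-09,4.04296601191785e-09,6.52727145217041e-09,0.652727145217041
1000,0.08,-5.63790115349352e-09,4.59957757878271e-09,7.27612831936079e-09,0.727612831936079
1000,0.12,-6.18698795638665e-09,5.22795843995648e-09,8.10002280381887e-09,0.810002280381887
1000,0.16,-6.77154276268529e-09,5.93701156274562e-09,9.00565920313725e-09,0.900565920313725
1000,0.2,-7.39072813278868e-09,6.73671712272752e-09,1.00003109913864e-08,1.00003109913864
1000,0.24,-8.04281026958255e-09,7.63825440753604e-09,1.10918766413419e-08,1.10918766413419
1000,0.28,-8.72491460292825e-09,8.65413355051003e-09,1.22889447202945e-08,1.22889447202945
1000,0.32,-9.43272500097445e-09,9.79833613107365e-09,1.36008709971645e-08,1.36008709971645
1000,0.36,-1.01601140592636e-08,1.10864627281395e-08,1.50378713094531e-08,1.50378713094531
1000,0.4,-1.08986891841804e-08,1.25358841410949e-08,1.66111353354407e-08,1.66111353354407
1000,0.44,-1.16372358974274e-08,1.41658910393177e-08,1.83329683431297e-08,1.83329683431297
1000,0.48,-1.2361035856578e-08,1.59978340466204e-08,2.02169706343659e-08,2.02169706343659
1000,0.52,-1.30510324303841e-08,1.80552424136099e-08,2.22782680231915e-08,2.22782680231915
1000,0.56,-1.36828112201738e-08,2.03639040742794e-08,2.45338116083369e-08,2.45338116083369
1000,0.6,-1.42253566540775e-08,2.29518824756537e-08,2.70027717301748e-08,2.70027717301748
1000,0.64,-1.46395387513586e-08,2.58494353716599e-08,2.97070598324061e-08,2.97070598324061
1000,0.68,-1.48762765541242e-08,2.90887867898994e-08,3.26720235220136e-08,3.26720235220136
1000,0.72,-1.48743169909645e-08,3.27036842805268e-08,3.59273749593269e-08,3.59273749593269
1000,0.76,-1.45575609138304e-08,3.67286475666248e-08,3.95084311487208e-08,3.95084311487208
1000,0.8,-1.38318632349216e-08,4.11977794934182e-08,4.34577665755833e-08,4.34577665755833
1000,0.84,-1.25812340339308e-08,4.61429626604692e-08,4.78274027405001e-08,4.78274027405001
1000,0.88,-1.06633764151532e-08,5.15912013817797e-08,5.26816823629104e-08,5.26816823629104
1000,0.92,-7.90452156763055e-09,5.75607837025264e-08,5.81009920884503e-08,5.81009920884503
1000,0.96,-4.09357273354679e-09,6.40558260830136e-08,6.41864954090977e-08,6.41864954090977
1000,1,1.02433539617872e-09,7.10586170949938e-08,7.10659997921425e-08,7.10659997921425
1000,1.04,7.75459058140488e-09,7.85189888111992e-08,7.89009840180617e-08,7.89009840180617
1000,1.08,1.64596236758967e-08,8.63397094887957e-08,8.78946223961499e-08,8.78946223961499
1000,1.12,2.75642019401514e-08,9.43566071899912e-08,9.83003283260221e-08,9.83003283260221
1000,1.16,4.15577883505446e-08,1.02311810878599e-07,1.10429871039709e-07,11.0429871039709
1000,1.2,5.89911449995038e-08,1.09818166879165e-07,1.24659476033925e-07,12.4659476033925
1000,1.24,8.04626409256278e-08,1.16312635339542e-07,1.41431487740022e-07,14.1431487740022
1000,1.28,1.06587121966957e-07,1.20996464325525e-07,1.61248128511549e-07,16.1248128511549
1000,1.32,1.37936330256163e-07,1.22760514563368e-07,1.84652579566061e-07,18.4652579566061
1000,1.36,1.74934243616055e-07,1.20095898512408e-07,2.12190985739319e-07,21.2190985739319
1000,1.4,2.17682822555004e-07,1.10994256698407e-07,2.44347163387557e-07,24.4347163387557
1000,1.44,2.65683158111734e-07,9.28505658828872e-08,2.8144052318207e-07,28.144052318207
1000,1.48,3.17404286524876e-07,6.23978784873153e-08,3.23479483652493e-07,32.3479483652493
1000,1.52,3.69639400251168e-07,1.57336923145251e-08,3.69974100839358e-07,36.9974100839358
1000,1.56,4.16584251223785e-07,-5.14489595385303e-08,4.19749251107466e-07,41.9749251107466
1000,1.6,4.48593893364076e-07,-1.43222535185025e-07,4.70902511936776e-07,47.0902511936776
1000,1.64,4.506643694328e-07,-2.6203145455977e-07,5.213049559087e-07,52.13049559087
1000,1.68,4.00937616552536e-07,-4.05989027775653e-07,5.7059448213337e-07,57.059448213337
1000,1.72,2.70127802481488e-07,-5.64061898135981e-07,6.25407750673305e-07,62.5407750673305
1000,1.76,2.40692737539296e-08,-7.08207187589883e-07,7.08616081170201e-07,70.8616081170201
1000,1.8,-3.65817975722916e-07,-7.82056898937162e-07,8.63386231380385e-07,86.3386231380385
1000,1.84,-8.94741580967326e-07,-6.88536431956524e-07,1.12900173376454e-06,112.900173376454
1000,1.88,-1.46366446527595e-06,-2.88115082534524e-07,1.49175197928322e-06,149.175197928322
1000,1.92,-1.76800339954839e-06,5.54536459448643e-07,1.85292922306075e-06,185.292922306075
1000,1.96,-1.15628799752489e-06,1.77429820613485e-06,2.11781398085702e-06,211.781398085702
1000,2,1.29544924433634e-06,2.54042360966514e-06,2.85165581043639e-06,285.165581043639
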