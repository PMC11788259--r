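x_cm,y_cm
2.32805745346882,0
2.33408562998258,0.20420603232224
2.42340376543749,0.427311468997117
2.4235735106424,0.649394564974091
2.39624119846689,0.87216047036432
2.37899932264344,1.10934560289419
2.42050751844569,1.39748066735013
2.30371007195413,1.61307515823191
2.19164674954237,1.83900997921189
2.04684901870286,2.04684901870285
1.87409523442056,2.23345972848438
1.60998726222348,2.29930009942465
1.38737319464025,2.40300086217606
1.15693623323904,2.48105775876938
0.903177616855614,2.48146010806764
0.641711128604226,2.39489853573334
0.423112077035275,2.39958783015084
0.209898069761863,2.39914591562675
1.46677537389521e-16,2.39542597084553
-0.209215304492896,2.39134187289194
-0.420944089567299,2.38729256223855
-0.656734360256254,2.45096599955258
-0.893531516095328,2.45495766404297
-1.11390220768173,2.38877099314435
-1.34452420979313,2.3287842433681
-1.58159349144903,2.25874959228923
-1.79349122273654,2.13739960798245
-1.9452280853267,1.9452280853267
-2.08122274431949,1.74635323715625
-2.1859107396223,1.5305911777371
-2.24405800628792,1.29560749400747
-2.29399283709666,1.06970642769089
-2.39139508466872,0.870396629189919
-2.37253159099306,0.635717923823918
-2.44184944833015,0.430563940568686
-2.45070871719098,0.214409230358372
-2.54051636006947,3.11123522854056e-16
-2.50224482706088,-0.218918055734212
-2.59340887620272,-0.45728795688336
-2.58289152936176,-0.69208369942967
-2.50415457312659,-0.911437726619665
-2.46348466757381,-1.14874176623709
-2.4054214735023,-1.38877073524106
-2.27459707952796,-1.59269002147527
-2.16619838752886,-1.81765626803229
-1.97703373596261,-1.9770337359626
-1.81626721344639,-2.16454297673581
-1.61034222035571,-2.29980703217368
-1.42615601337863,-2.47017467469166
-1.1804463345102,-2.53147533364726
-0.964753556625473,-2.65063861216702
-0.727433662142414,-2.71481938625138
-0.493282598645666,-2.79754463363295
-0.245698208944118,-2.80834337892605
-5.15667521333136e-16,-2.80716323918681
0.245290692302184,-2.80368544239451
0.480520497991762,-2.72516716421434
0.716096891765788,-2.67250998321207
0.946961066523138,-2.60175414737499
1.14916645708129,-2.46439542002828
1.38484785157783,-2.39862683968541
1.5565647895189,-2.22300490151638
1.77028860515392,-2.10974780512078
1.93478797068616,-1.93478797068616
2.05852897647876,-1.72731090493107
2.17521078551229,-1.52309898921077
2.25738665598481,-1.3033027934979
2.32400122829432,-1.08369957031527
2.32736019109424,-0.847089833974405
2.31496813991764,-0.620293843594711
2.3225576189537,-0.409529572471549
2.32479698906838,-0.203393381542685
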