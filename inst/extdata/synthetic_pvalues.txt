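50
t01 0.00585792909598876
t02 0.178705591547072
t03 0.0162081943884649
t04 0.0277302369335021
t05 0.0912067831066865
t06 0.697103886019579
t07 0.10296197778956
t08 0.163573236837571
t09 0.0172766702594977
t10 0.0634789091340278
t11 0.341558025917038
t12 0.343438799958676
t13 0.232562693301588
t14 0.0613688277080655
t15 0.412376251770183
t16 0.185512177180499
t17 0.410672063706443
t18 0.140080855693668
t19 0.00543451681733131
t20 0.60173881566152
t21 0.91101012728177
t22 0.175362783949822
t23 0.731187413213775
t24 0.0161572096403688
t25 0.586115716258064
t26 0.425818428397179
t27 0.210490977624431
t28 0.477200108347461
t29 0.75482327491045
t30 0.446829279884696
t31 0.371201802045107
t32 0.874778404599056
t33 0.434597307350487
t34 0.440136776538566
t35 0.0819568333681673
t36 0.034619303420186
t37 0.928651981754228
t38 0.294566297205165
t39 0.519224287476391
t40 0.236396424937993
t41 0.971809808630496
t42 0.632511501200497
t43 0.958269165828824
t44 0.8863539788872
t45 0.523183763725683
t46 0.715915634296834
t47 0.740642732940614
t48 0.0458963238634169
t49 0.957792913774028
t50 0.201136683113873
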