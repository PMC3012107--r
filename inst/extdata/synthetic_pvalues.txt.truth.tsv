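id	truth
t01	TRUE
t02	TRUE
t03	TRUE
t04	TRUE
t05	TRUE
t06	TRUE
t07	TRUE
t08	TRUE
t09	TRUE
t10	TRUE
t11	FALSE
t12	FALSE
t13	FALSE
t14	FALSE
t15	FALSE
t16	FALSE
t17	FALSE
t18	FALSE
t19	FALSE
t20	FALSE
t21	FALSE
t22	FALSE
t23	FALSE
t24	FALSE
t25	FALSE
t26	FALSE
t27	FALSE
t28	FALSE
t29	FALSE
t30	FALSE
t31	FALSE
t32	FALSE
t33	FALSE
t34	FALSE
t35	FALSE
t36	FALSE
t37	FALSE
t38	FALSE
t39	FALSE
t40	FALSE
t41	FALSE
t42	FALSE
t43	FALSE
t44	FALSE
t45	FALSE
t46	FALSE
t47	FALSE
t48	FALSE
t49	FALSE
t50	FALSE
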