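country,score,rank
Australia,0.991,1
Greece,0.987,2
Korea,0.957,3
Iceland,0.955,4
Mexico,0.955,5
Switzerland,0.953,6
Sweden,0.947,7
Germany,0.944,8
Japan,0.943,9
France,0.939,10
Canada,0.935,11
Netherlands,0.935,12
Portugal,0.933,13
Austria,0.932,14
Norway,0.922,15
Belgium,0.917,16
New Zealand,0.917,17
Luxembourg,0.916,18
Poland,0.914,19
Ireland,0.911,20
Finland,0.908,21
Spain,0.905,22
Denmark,0.899,23
Czech Republic,0.895,24
United Kingdom,0.891,25
Italy,0.824,26
Hungary,0.812,27
Slovak Republic,0.808,28
Turkey,0.805,29
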