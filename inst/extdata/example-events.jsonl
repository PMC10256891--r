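{"kind":"header","schema":"jitai-events/1","tz":"UTC"}
{"kind":"report","t":"2021-01-04T10:00:00+0000","lat":52.63,"lon":1.297,"urge":4,"stress":2,"mood":2,"situation":"home","others":false}
{"kind":"report","t":"2021-01-04T10:20:00+0000","lat":52.6301,"lon":1.2971,"urge":3,"stress":2,"mood":2,"situation":"home","others":false}
{"kind":"report","t":"2021-01-04T12:30:00+0000","lat":52.641,"lon":1.309,"urge":3,"stress":4,"mood":2,"situation":"work","others":false}
{"kind":"report","t":"2021-01-05T12:40:00+0000","lat":52.641,"lon":1.309,"urge":3,"stress":2,"mood":2,"situation":"work","others":false}
{"kind":"reset","t":"2021-01-10T09:00:00+0000","quit_date":"2021-01-11"}
{"kind":"fix","t":"2021-01-12T10:00:00+0000","lat":52.63,"lon":1.297,"acc":10}
{"kind":"fix","t":"2021-01-12T10:05:00+0000","lat":52.63,"lon":1.297,"acc":10}
{"kind":"fix","t":"2021-01-12T13:10:00+0000","lat":52.641,"lon":1.309,"acc":10}
{"kind":"fix","t":"2021-01-12T13:15:00+0000","lat":52.641,"lon":1.309,"acc":10}
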